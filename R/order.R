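## Steinhardt bond-orientational order parameters at molecular geometric
## centers, and the solid/liquid classification built on them.

#' Complex spherical harmonics Y_lm on the unit sphere
#'
#' Orthonormal spherical harmonics with the Condon-Shortley phase,
#' evaluated for all `m = -l..l` at the given directions via the standard
#' normalized associated-Legendre recurrence (stable for the small `l`
#' used by bond-order parameters).
#'
#' @param l non-negative integer order.
#' @param theta polar angles (radians, from +z).
#' @param phi azimuthal angles (radians).
#' @return complex matrix, `length(theta)` x `(2l+1)`; columns ordered
#'   `m = -l, ..., +l`.
#' @examples
#' Y <- sphericalHarmonics(6, pi / 3, pi / 4)
#' sum(Mod(Y)^2) * 4 * pi / 13   # addition theorem: 1
#' @export
sphericalHarmonics <- function(l, theta, phi) {
  stopifnot(l >= 0, length(theta) == length(phi))
  x <- cos(theta)
  npt <- length(x)
  ## normalized P~_l^m(x) including sqrt((2l+1)/(4pi) (l-m)!/(l+m)!)
  P <- matrix(NA_real_, npt, l + 1)              # columns m = 0..l
  for (m in 0:l) {
    ## seed P~_m^m = (-1)^m sqrt((2m+1)/(4pi) (2m-1)!!/(2m)!!) (1-x^2)^(m/2)
    pmm <- rep(sqrt((2 * m + 1) / (4 * pi)), npt)
    if (m > 0) {
      somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
      pmm <- pmm * prod(sqrt(1 - 1 / (2 * seq_len(m)))) * (-somx2)^m
    }
    if (l == m) { P[, m + 1] <- pmm; next }
    pmmp1 <- x * sqrt(2 * m + 3) * pmm
    if (l == m + 1) { P[, m + 1] <- pmmp1; next }
    for (ll in (m + 2):l) {
      c1 <- sqrt((4 * ll^2 - 1) / (ll^2 - m^2))
      c2 <- sqrt(((ll - 1)^2 - m^2) / (4 * (ll - 1)^2 - 1))
      pll <- c1 * (x * pmmp1 - c2 * pmm)
      pmm <- pmmp1; pmmp1 <- pll
    }
    P[, m + 1] <- pmmp1
  }
  Y <- matrix(complex(real = 0, imaginary = 0), npt, 2 * l + 1)
  for (m in 0:l) {
    e <- exp(complex(imaginary = m * phi))
    Y[, l + 1 + m] <- P[, m + 1] * e
    if (m > 0) Y[, l + 1 - m] <- (-1)^m * Conj(Y[, l + 1 + m])
  }
  Y
}

#' Find neighbors under minimum-image periodic boundary conditions
#'
#' Builds a per-molecule neighbor list with minimum-image displacement
#' vectors, using either a distance cutoff (symmetric criterion) or the
#' k-nearest neighbors.  Lists are indexed by molecule id with neighbors
#' ordered by increasing distance (ties by id), so the result is
#' deterministic.
#'
#' @param frame a [Frame-class].
#' @param cutoff cutoff radius, nm; must stay below half the smallest box
#'   edge (image ambiguity otherwise).
#' @param k number of nearest neighbors (used when `cutoff` is NULL).
#' @return a [NeighborList-class].
#' @examples
#' fr <- makeFrame(rbind(c(0.1, 0, 0), c(9.9, 0, 0)), box = c(10, 10, 10))
#' neighborIds(findNeighbors(fr, cutoff = 0.5), 1)   # periodic neighbor
#' @export
findNeighbors <- function(frame, cutoff = NULL, k = NULL) {
  stopifnot(is(frame, "Frame"))
  box <- boxEdges(frame)
  xyz <- positions(frame)
  n <- nrow(xyz)
  if (is.null(cutoff) && is.null(k))
    stop("give either a cutoff radius or a neighbor count k")
  if (!is.null(cutoff) && cutoff >= min(box) / 2)
    stop("cutoff must be below half the smallest box edge")
  if (!is.null(k) && (k < 1 || k >= n))
    stop("k must be in [1, n-1]")
  idx <- vector("list", n)
  disp <- vector("list", n)
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    rows <- i0:min(i0 + chunk - 1L, n)
    d2 <- matrix(0, length(rows), n)
    dAx <- vector("list", 3)
    for (ax in 1:3) {
      da <- outer(xyz[rows, ax], xyz[, ax], `-`)
      da <- da - box[ax] * round(da / box[ax])
      dAx[[ax]] <- da
      d2 <- d2 + da * da
    }
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d2[r, ]
      di[i] <- Inf
      if (!is.null(cutoff)) {
        js <- which(di <= cutoff^2)
      } else {
        js <- order(di)[seq_len(k)]
      }
      js <- js[order(di[js], js)]
      idx[[i]] <- as.integer(js)
      disp[[i]] <- cbind(-dAx[[1]][r, js], -dAx[[2]][r, js], -dAx[[3]][r, js])
    }
  }
  crit <- if (!is.null(cutoff)) list(type = "cutoff", cutoff = cutoff)
          else list(type = "knn", k = as.integer(k))
  new("NeighborList", idx = idx, disp = disp, criterion = crit)
}

#' Steinhardt bond-orientational order parameter q_l
#'
#' For each molecule `i`, `q_lm(i)` is the mean of `Y_lm` over the unit
#' bond vectors to its neighbors, and
#' `q_l(i) = sqrt(4*pi/(2l+1) * sum_m |q_lm(i)|^2)`.  The neighbor-averaged
#' variant re-averages `q_lm` over the molecule and its neighbors before
#' the contraction, which sharpens the solid/liquid contrast.  Values lie
#' in `[0, 1]` and are invariant under global rotations and translations.
#' A molecule with a single neighbor gives exactly 1 (spherical-harmonic
#' addition theorem).  Isolated molecules are flagged (`NA` value) and a
#' warning is logged.
#'
#' @param frame a [Frame-class].
#' @param neighbors a [NeighborList-class] for the frame.
#' @param l even spherical-harmonic order (default 6).
#' @param averaged use the neighbor-averaged variant (default TRUE).
#' @return an [OrderField-class].
#' @examples
#' fr <- makeFrame(rbind(c(5, 5, 5), c(5.3, 5, 5)), box = c(10, 10, 10))
#' orderValues(steinhardtQ(fr, findNeighbors(fr, k = 1)))   # both 1
#' @export
steinhardtQ <- function(frame, neighbors, l = 6L, averaged = TRUE) {
  stopifnot(is(frame, "Frame"), is(neighbors, "NeighborList"))
  l <- as.integer(l)
  if (l %% 2L != 0L) stop("l must be even for a crystal order parameter")
  n <- nMolecules(frame)
  counts <- lengths(neighbors@idx)
  flagged <- counts == 0L
  if (any(flagged))
    warning(sum(flagged), " isolated molecule(s) flagged and excluded")
  ## stack all bond vectors, evaluate Y_lm once, then average per molecule
  owner <- rep.int(seq_len(n), counts)
  allDisp <- do.call(rbind, neighbors@disp[counts > 0])
  r <- sqrt(rowSums(allDisp^2))
  theta <- acos(pmin(1, pmax(-1, allDisp[, 3] / r)))
  phi <- atan2(allDisp[, 2], allDisp[, 1])
  Y <- sphericalHarmonics(l, theta, phi)
  sumRe <- rowsum(Re(Y), owner, reorder = TRUE)
  sumIm <- rowsum(Im(Y), owner, reorder = TRUE)
  present <- sort(unique(owner))
  qlmFull <- matrix(complex(real = NA_real_), n, 2 * l + 1)
  qlmFull[present, ] <- complex(real = sumRe, imaginary = sumIm) /
    counts[present]
  if (averaged) {
    qbar <- qlmFull
    for (i in which(!flagged)) {
      members <- c(i, neighbors@idx[[i]])
      members <- members[!flagged[members]]
      qbar[i, ] <- colMeans(qlmFull[members, , drop = FALSE])
    }
    qlmFull <- qbar
  }
  vals <- sqrt(4 * pi / (2 * l + 1) * rowSums(Mod(qlmFull)^2))
  vals[flagged] <- NA_real_
  new("OrderField", values = pmin(vals, 1), l = l, averaged = averaged,
      criterion = neighbors@criterion, flagged = flagged)
}

#' Classify molecules as solid-like or liquid-like
#'
#' A molecule is solid iff its order-parameter value is at or above the
#' threshold.  When no threshold is given it defaults to the midpoint of
#' the fitted bulk levels `(oS + oL)/2` if an [InterfaceProfileFit-class]
#' is supplied, and otherwise to the midpoint of a two-means split of the
#' order values (the bulk levels are well separated in biphasic systems,
#' so the split recovers them).  Flagged (isolated) molecules are labeled
#' `"unknown"`.
#'
#' @param order an [OrderField-class].
#' @param threshold classification threshold in `[0, 1]`, or NULL.
#' @param fit optional [InterfaceProfileFit-class] supplying the bulk
#'   levels.
#' @return character vector of `"solid"` / `"liquid"` / `"unknown"`.
#' @export
classifyPhase <- function(order, threshold = NULL, fit = NULL) {
  stopifnot(is(order, "OrderField"))
  if (is.null(threshold)) {
    if (!is.null(fit)) {
      stopifnot(is(fit, "InterfaceProfileFit"))
      threshold <- (fit@oS + fit@oL) / 2
    } else {
      v <- orderValues(order)
      v <- v[!order@flagged & !is.na(v)]
      km <- stats::kmeans(v, centers = range(v))
      threshold <- mean(km$centers)
    }
  }
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  out <- ifelse(orderValues(order) >= threshold, "solid", "liquid")
  out[order@flagged] <- "unknown"
  out
}
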