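.minImage <- function(d, L) d - L * round(d / L)

# Minimum-image-consistent unwrapping of an aggregate: each chain is unwrapped
# internally relative to its first bead, then whole chains are shifted by
# lattice vectors toward the running mean of already-placed chain centers.
# Valid for aggregates smaller than half the box in every direction.
.unwrapAggregate <- function(pos, moleculeId, box) {
  chains <- split(seq_len(nrow(pos)), moleculeId)
  out <- pos
  coms <- matrix(0, length(chains), 3)
  for (ci in seq_along(chains)) {
    idx <- chains[[ci]]
    p <- pos[idx, , drop = FALSE]
    if (nrow(p) > 1)
      for (k in 2:nrow(p))
        p[k, ] <- p[k - 1, ] + .minImage(p[k, ] - p[k - 1, ], box)
    if (ci > 1) {
      ref <- colMeans(coms[seq_len(ci - 1), , drop = FALSE])
      shift <- -box * round((colMeans(p) - ref) / box)
      p <- sweep(p, 2, shift, "+")
    }
    coms[ci, ] <- colMeans(p)
    out[idx, ] <- p
  }
  out
}

#' Detect aggregates by single-linkage clustering of chains
#'
#' Two chains belong to the same aggregate when any pair of their beads of
#' \code{linkageSpecies} lies within \code{cutoff} under the minimum-image
#' convention; aggregates are the connected components of that contact graph
#' (single linkage, so membership is transitive). The hydrophobic core
#' species defines micelle membership, hence the PPO default; report results
#' together with the cutoff used.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param cutoff contact distance, nm (default 1.3 sigma = 1.36 nm).
#' @param linkageSpecies species whose bead contacts join chains.
#' @return list of \linkS4class{Aggregate} objects partitioning the chains.
#' @export
findAggregates <- function(state, cutoff = 1.36, linkageSpecies = "PPO") {
  if (cutoff <= 0) stop("cutoff must be positive")
  link <- which(state@species %in% linkageSpecies)
  chainIds <- sort(unique(state@moleculeId[link]))
  nc <- length(chainIds)
  if (nc == 0) return(list())
  memb <- if (nc == 1) {
    1L
  } else {
    p <- state@positions[link, , drop = FALSE]
    chainOf <- match(state@moleculeId[link], chainIds)
    # all-pairs minimum-image distances between linkage beads
    adj <- matrix(FALSE, nc, nc)
    cut2 <- cutoff^2
    for (d in 1:3) {
      dd <- .minImage(outer(p[, d], p[, d], "-"), state@box[d])^2
      if (d == 1) d2 <- dd else d2 <- d2 + dd
    }
    close <- which(d2 <= cut2, arr.ind = TRUE)
    ci <- chainOf[close[, 1]]
    cj <- chainOf[close[, 2]]
    keep <- ci < cj
    g <- igraph::graph_from_edgelist(cbind(ci[keep], cj[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nc - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  lapply(seq_len(max(memb)), function(a) {
    mols <- chainIds[memb == a]
    beads <- which(state@moleculeId %in% mols)
    unw <- .unwrapAggregate(state@positions[beads, , drop = FALSE],
                            state@moleculeId[beads], state@box)
    com <- .wrap(colMeans(unw), state@box)
    new("Aggregate", chainIds = as.integer(mols),
        beadIndices = as.integer(beads), com = com,
        size = length(mols))
  })
}

#' Number-average aggregation number
#'
#' <P>_n = sum_i P_i n_i where n_i is the fraction of aggregates whose
#' aggregation number equals P_i (sum_i n_i = 1) -- i.e. the number average of
#' the aggregate sizes. Unimers count by default; \code{minSize} supports
#' bookkeeping that treats free chains separately.
#'
#' @param aggregates list of \linkS4class{Aggregate} objects, or a numeric
#'   vector of aggregate sizes.
#' @param minSize smallest aggregate size included.
#' @return the mean aggregation number.
#' @examples
#' meanAggregationNumber(c(5, 5, 3, 1))   # 3.5
#' @export
meanAggregationNumber <- function(aggregates, minSize = 1) {
  sizes <- if (is.numeric(aggregates)) aggregates
           else vapply(aggregates, function(a) as.numeric(a@size), numeric(1))
  sizes <- sizes[sizes >= minSize]
  if (length(sizes) == 0)
    stop("undefined statistic: no aggregates of size >= ", minSize)
  mean(sizes)
}

#' Gyration-tensor shape descriptors of one aggregate
#'
#' Builds the 3x3 gyration tensor S_ab = (1/n) sum_i (a_i - a_cm)(b_i - b_cm)
#' over the aggregate's beads after minimum-image-consistent unwrapping,
#' diagonalizes it, and reports the ascending eigenvalues, Rg^2 = lambda1 +
#' lambda2 + lambda3, the core-only Rg (about the core beads' own center of
#' mass), and the asphericity
#' Q = [(l2-l1)^2 + (l3-l1)^2 + (l3-l2)^2] / [2 (l1+l2+l3)^2],
#' which is 0 for a sphere and 1 for a rod. A single bead yields a zero
#' tensor and Q = 0 by convention.
#'
#' @param aggregate an \linkS4class{Aggregate}.
#' @param state the \linkS4class{SimulationState} it was detected in.
#' @param coreSpecies species forming the micellar core.
#' @return a \linkS4class{ShapeDescriptors}.
#' @export
shapeDescriptors <- function(aggregate, state, coreSpecies = "PPO") {
  beads <- aggregate@beadIndices
  unw <- .unwrapAggregate(state@positions[beads, , drop = FALSE],
                          state@moleculeId[beads], state@box)
  tensor <- function(p) {
    centered <- sweep(p, 2, colMeans(p))
    crossprod(centered) / nrow(p)
  }
  lam <- sort(pmax(eigen(tensor(unw), symmetric = TRUE,
                         only.values = TRUE)$values, 0))
  core <- which(state@species[beads] %in% coreSpecies)
  rgCore <- if (length(core) > 0)
    sqrt(sum(diag(tensor(unw[core, , drop = FALSE])))) else NA_real_
  denom <- sum(lam)
  q <- if (denom > 0)
    ((lam[2] - lam[1])^2 + (lam[3] - lam[1])^2 + (lam[3] - lam[2])^2) /
      (2 * denom^2) else 0
  new("ShapeDescriptors", lambda = lam, rg = sqrt(sum(lam)),
      rgCore = rgCore, q = min(max(q, 0), 1))
}

#' Mean radial density profile around micelle centers of mass
#'
#' For each aggregate: compute its COM, bin every bead of the system by its
#' minimum-image distance to that COM, divide the per-species counts by the
#' shell volume (4 pi/3)(r_out^3 - r_in^3), then average the shell densities
#' over all micelles with equal weight.
#'
#' @param aggregates list of \linkS4class{Aggregate} objects (the micelle
#'   centers), or a single Aggregate.
#' @param state a \linkS4class{SimulationState}.
#' @param binWidth shell width, nm.
#' @param rMax largest radius, nm (default half the shortest box edge).
#' @param minSize smallest aggregate used as a center.
#' @return a \linkS4class{RadialProfile}.
#' @export
radialDensityProfile <- function(aggregates, state, binWidth = 0.5,
                                 rMax = NULL, minSize = 1) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (is(aggregates, "Aggregate")) aggregates <- list(aggregates)
  aggregates <- Filter(function(a) a@size >= minSize, aggregates)
  if (length(aggregates) == 0) stop("no aggregates to average over")
  if (is.null(rMax)) rMax <- min(state@box) / 2
  edges <- seq(0, rMax, by = binWidth)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  nbin <- length(edges) - 1
  lev <- levels(state@species)
  shellVol <- (4 * pi / 3) * diff(edges^3)
  acc <- matrix(0, nbin, length(lev), dimnames = list(NULL, lev))
  for (agg in aggregates) {
    d <- sqrt(rowSums(vapply(1:3, function(dd)
      .minImage(state@positions[, dd] - agg@com[dd], state@box[dd])^2,
      numeric(nrow(state@positions)))))
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nbin
    counts <- table(factor(bin[ok], levels = seq_len(nbin)),
                    state@species[ok])
    acc <- acc + unclass(counts) / shellVol
  }
  new("RadialProfile", binEdges = edges,
      density = acc / length(aggregates), species = lev,
      nMicelles = length(aggregates))
}

#' Time-origin-averaged mean squared displacement
#'
#' MSD(tau) averaged over all time origins and over the selected beads (or
#' molecule centers of mass), from unwrapped coordinates.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param species optional species subset.
#' @param byMolecule average positions within each molecule first.
#' @param lags frame-lag values (default: every available lag).
#' @return data.frame with columns \code{lag} (frames), \code{time} (ps) and
#'   \code{msd} (nm^2).
#' @export
meanSquaredDisplacement <- function(trajectory, species = NULL,
                                    byMolecule = FALSE, lags = NULL) {
  nf <- length(trajectory@unwrapped)
  if (nf < 2) stop("insufficient data: need at least 2 frames")
  keep <- if (is.null(species)) seq_along(trajectory@species)
          else which(trajectory@species %in% species)
  coords <- lapply(trajectory@unwrapped, function(p) {
    p <- p[keep, , drop = FALSE]
    if (byMolecule) {
      mol <- trajectory@moleculeId[keep]
      rowsum(p, mol) / as.vector(table(mol))
    } else p
  })
  if (is.null(lags)) lags <- seq_len(nf - 1)
  lags <- sort(unique(lags[lags >= 1 & lags <= nf - 1]))
  msd <- vapply(lags, function(l) {
    s <- 0
    for (t0 in seq_len(nf - l))
      s <- s + mean(rowSums((coords[[t0 + l]] - coords[[t0]])^2))
    s / (nf - l)
  }, numeric(1))
  steps <- trajectory@steps
  dtFrame <- if (nf > 1) diff(steps)[1] * trajectory@dt else trajectory@dt
  data.frame(lag = lags, time = lags * dtFrame, msd = msd)
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD versus time over a window of the lag range,
#' divided by 6.
#'
#' @param msd data.frame from \code{\link{meanSquaredDisplacement}}.
#' @param window fraction of the maximum lag used for the linear fit.
#' @return D in nm^2/ps.
#' @export
diffusionCoefficient <- function(msd, window = c(0.2, 0.6)) {
  tmax <- max(msd$time)
  sel <- msd$time >= window[1] * tmax & msd$time <= window[2] * tmax
  if (sum(sel) < 2) sel <- rep(TRUE, nrow(msd))
  stats::coef(stats::lm(msd ~ time, data = msd[sel, ]))[["time"]] / 6
}

#' Per-frame aggregate summary of a trajectory
#'
#' Runs aggregate detection and shape analysis on every stored frame and
#' returns a tidy table (one row per aggregate per frame).
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param cutoff,linkageSpecies passed to \code{\link{findAggregates}}.
#' @param coreSpecies passed to \code{\link{shapeDescriptors}}.
#' @return data.frame with frame, step, aggregate, size, rg, rgCore,
#'   lambda1..3, q.
#' @export
aggregateTimeSeries <- function(trajectory, cutoff = 1.36,
                                linkageSpecies = "PPO", coreSpecies = "PPO") {
  frames <- seq_along(trajectory@positions)
  out <- lapply(frames, function(fi) {
    st <- .frameState(trajectory, fi)
    aggs <- findAggregates(st, cutoff, linkageSpecies)
    if (length(aggs) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(aggs), function(ai) {
      sd <- shapeDescriptors(aggs[[ai]], st, coreSpecies)
      data.frame(frame = fi, step = trajectory@steps[fi], aggregate = ai,
                 size = aggs[[ai]]@size, rg = sd@rg, rgCore = sd@rgCore,
                 lambda1 = sd@lambda[1], lambda2 = sd@lambda[2],
                 lambda3 = sd@lambda[3], q = sd@q)
    }))
  })
  do.call(rbind, out)
}

# Materialize frame fi of a trajectory as a SimulationState.
.frameState <- function(trajectory, fi) {
  new("SimulationState", positions = trajectory@positions[[fi]],
      velocities = matrix(0, nrow(trajectory@positions[[fi]]), 3),
      species = trajectory@species, moleculeId = trajectory@moleculeId,
      bonds = trajectory@bonds, box = trajectory@box,
      step = trajectory@steps[fi], rngSeed = 0L)
}

#' @rdname aggregateTimeSeries
#' @param ... passed to \code{findAggregates}.
#' @return for \code{aggregationNumberSeries}: data.frame with step and Pn.
#' @export
aggregationNumberSeries <- function(trajectory, ...) {
  pn <- vapply(seq_along(trajectory@positions), function(fi) {
    aggs <- findAggregates(.frameState(trajectory, fi), ...)
    meanAggregationNumber(aggs)
  }, numeric(1))
  data.frame(step = trajectory@steps, Pn = pn)
}
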