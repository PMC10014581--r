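#' Fuzzy c-means clustering of temporal trajectories
#'
#' Standard fuzzy c-means with Euclidean distance: centroid and membership
#' updates alternate until the largest centroid shift drops below `tol` or
#' `max_iter` is reached. Memberships per row sum to 1 and the objective
#' `sum_ik u_ik^m d_ik^2` is non-increasing across iterations. Deterministic
#' given `seed` (initial centroids are `k` distinct rows sampled from the
#' data).
#'
#' @param traj A numeric matrix (rows = peaks, columns = stages), typically
#'   from [standardize_trajectories()].
#' @param k Number of clusters (default 8).
#' @param fuzzifier_m Fuzziness exponent m > 1 (default 1.25, suited to
#'   z-scored trajectories).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the maximum centroid coordinate shift.
#' @param seed Integer seed for the centroid initialisation.
#' @return An `enhancer_classification` object: fields `membership` (row-
#'   stochastic peak x cluster matrix), `centers` (k x stages), `hard_cluster`,
#'   `membership_score`, `objective` (per-iteration trace), `converged`,
#'   `group` (NA until [assign_groups()]).
#' @export
cmeans_cluster <- function(traj, k = 8, fuzzifier_m = 1.25,
                           max_iter = 1000, tol = 1e-6, seed = 1) {
  traj <- as.matrix(traj)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (nrow(traj) < k) stop("need at least k rows to cluster", call. = FALSE)
  if (fuzzifier_m <= 1) stop("fuzzifier_m must be > 1", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # initial centroids: k distinct data rows
  centers <- traj[sample(nrow(traj), k), , drop = FALSE]
  objective <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(traj, centers)
    u <- fcm_memberships(d2, fuzzifier_m)
    objective <- c(objective, sum(u^fuzzifier_m * d2))
    um <- u^fuzzifier_m
    new_centers <- crossprod(um, traj) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fuzzy c-means did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  # memberships consistent with the final centroids
  d2 <- sq_dist(traj, centers)
  u <- fcm_memberships(d2, fuzzifier_m)
  rownames(u) <- rownames(traj)
  colnames(u) <- paste0("cluster", seq_len(k))
  rownames(centers) <- colnames(u)
  hard <- max.col(u, ties.method = "first")
  structure(
    list(membership = u,
         centers = centers,
         hard_cluster = stats::setNames(hard, rownames(traj)),
         membership_score = stats::setNames(apply(u, 1, max), rownames(traj)),
         group = NULL,
         cluster_groups = NULL,
         objective = objective,
         converged = converged,
         k = k, fuzzifier_m = fuzzifier_m, seed = seed,
         stages = colnames(traj)),
    class = "enhancer_classification"
  )
}

sq_dist <- function(x, centers) {
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  pmax(outer(xs, cs, "+") - 2 * tcrossprod(x, centers), 0)
}

fcm_memberships <- function(d2, m) {
  expo <- 1 / (m - 1)
  inv <- d2^(-expo)
  zero <- d2 <= .Machine$double.eps
  u <- inv / rowSums(inv)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    # a point sitting on >=1 centroid splits its membership among them
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' @export
print.enhancer_classification <- function(x, ...) {
  cat(sprintf(
    "enhancer_classification: %d peaks, k = %d (m = %g), %s\n",
    nrow(x$membership), x$k, x$fuzzifier_m,
    if (is.null(x$group)) "groups unassigned" else
      paste(length(unique(x$group)), "named groups")))
  invisible(x)
}

#' Reference temporal archetypes for the six enhancer groups
#'
#' Z-scored stage profiles encoding the canonical shapes over the five-stage
#' endoderm time course (ESC, ADE, VFGp3, VFGp6, PE): `ADE^OFF` closes upon
#' ADE induction; `VFG^OFF` opens at ADE then closes during VFG expansion;
#' `PE^OFF` stays open through VFG and closes only at PE; `PE^ON` opens only
#' at PE; `VFG^TR` is transiently open during VFG; `PE^PRIMED` rises
#' monotonically into PE.
#'
#' @param stages Stage labels (length 5 by default).
#' @return A group-by-stage matrix of z-scored profiles.
#' @export
enhancer_archetypes <- function(stages = c("ESC", "ADE", "VFGp3", "VFGp6", "PE")) {
  zscore_rows(archetype_shapes(stages))
}

# raw accessibility shapes on a 0..1 scale (1 = fully open); shared by the
# archetype library and the synthetic count generator
archetype_shapes <- function(stages = c("ESC", "ADE", "VFGp3", "VFGp6", "PE")) {
  shapes <- rbind(
    "ADE^OFF"   = c(1, 0, 0, 0, 0),
    "VFG^OFF"   = c(0, 1, 0.5, 0, 0),
    "PE^OFF"    = c(0, 1, 1, 1, 0),
    "PE^ON"     = c(0, 0, 0, 0, 1),
    "VFG^TR"    = c(0, 0.25, 1, 1, 0),
    "PE^PRIMED" = c(0, 0.25, 0.5, 0.75, 1)
  )
  if (length(stages) != ncol(shapes)) {
    stop("archetypes are defined over 5 stages", call. = FALSE)
  }
  colnames(shapes) <- stages
  shapes
}

#' Name c-means clusters by their best-matching archetype
#'
#' Each cluster centroid is assigned to the archetype with the highest
#' Pearson correlation; several centroids may map to the same group (the
#' 8-to-6 merge). Correlation ties break deterministically by archetype
#' order, with a warning.
#'
#' @param classification An `enhancer_classification` from [cmeans_cluster()].
#' @param archetypes Named group-by-stage profile matrix
#'   (default [enhancer_archetypes()]).
#' @return The classification with `group` (per peak) and `cluster_groups`
#'   (the centroid-to-group assignment table) filled in.
#' @export
assign_groups <- function(classification, archetypes = enhancer_archetypes(classification$stages)) {
  cors <- stats::cor(t(classification$centers), t(archetypes))
  best <- apply(cors, 1, function(r) {
    top <- which(r >= max(r) - 1e-12)
    if (length(top) > 1) {
      warning("archetype correlation tie broken by list order", call. = FALSE)
    }
    top[1]
  })
  cluster_groups <- tibble::tibble(
    cluster = rownames(classification$centers),
    group = rownames(archetypes)[best],
    correlation = cors[cbind(seq_along(best), best)]
  )
  classification$cluster_groups <- cluster_groups
  classification$group <- stats::setNames(
    cluster_groups$group[classification$hard_cluster],
    names(classification$hard_cluster)
  )
  classification
}
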