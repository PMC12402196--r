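# Rigid surface registration: closed-form correspondence fit (SVD of the
# cross-covariance, reflection-corrected) and point-to-point iterative
# closest point. Used twice per posture pair: postures are first aligned on
# the talus, then the neutral calcaneus is registered to the talus-aligned
# counterpart, yielding the calcaneus motion in the talus frame.

#' ICP parameters
#'
#' @param max_iterations Maximum ICP iterations (>= 1).
#' @param convergence_tol Convergence threshold on the change in rms (mm).
#' @param subsample Number of source points used for correspondences, or
#'   `Inf` for all. Subsampling is a seeded draw, so results are
#'   reproducible.
#' @param seed Integer seed for the subsample draw.
#' @return Object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100, convergence_tol = 1e-8,
                       subsample = Inf, seed = 1L) {
  stopifnot(max_iterations >= 1, convergence_tol > 0, subsample >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol, subsample = subsample,
                 seed = as.integer(seed)),
            class = "icp_params")
}

as_points <- function(x) {
  if (inherits(x, "surface_mesh")) return(x$vertices)
  x <- as.matrix(x)
  stopifnot(is.numeric(x), ncol(x) == 3)
  x
}

#' Closed-form rigid fit to point correspondences
#'
#' Returns the rigid transform minimising `sum_i ||T(p_i) - q_i||^2` for
#' paired points, via SVD of the cross-covariance matrix with reflection
#' correction so the rotation has determinant +1 (the Kabsch/Umeyama
#' solution).
#'
#' @param P,Q n x 3 matrices of corresponding points (rows paired), n >= 3,
#'   not collinear.
#' @return A [rigid_transform] mapping `P` onto `Q`.
#' @export
rigid_fit_correspondences <- function(P, Q) {
  P <- as_points(P); Q <- as_points(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must be paired", call. = FALSE)
  if (nrow(P) < 3) stop("need at least 3 correspondences", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] <= 1e-9 * max(svd(Pc)$d[1], 1))
    stop("correspondences are (near) collinear", call. = FALSE)
  W <- crossprod(Pc, Qc)               # 3x3 cross-covariance
  sv <- svd(W)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

# index of nearest row of `tgt` for each row of `src` (brute force, blocked
# to bound memory)
nearest_indices <- function(src, tgt, block = 2048L) {
  t2 <- rowSums(tgt^2)
  out <- integer(nrow(src))
  for (i0 in seq(1L, nrow(src), by = block)) {
    i1 <- min(i0 + block - 1L, nrow(src))
    D <- -2 * src[i0:i1, , drop = FALSE] %*% t(tgt)
    D <- sweep(D, 2, t2, "+")
    out[i0:i1] <- max.col(-D, ties.method = "first")
  }
  out
}

# Candidate initial alignments: identity; centroid shift; the four
# proper-rotation principal-axes alignments (sign-ambiguous axis pairings);
# and a coarse grid of single-axis rotations about the centroid. Point-to-
# point ICP is a local method; with postures repositioned by tens of degrees
# between scans the identity basin is not guaranteed, principal axes can be
# poorly separated on compact bones, and the rotation grid covers the
# placement range either way.
icp_init_candidates <- function(S, Tg) {
  pca_basis <- function(P) {
    V <- svd(sweep(P, 2, colMeans(P)))$v
    if (det(V) < 0) V[, 3] <- -V[, 3]
    V
  }
  Vs <- pca_basis(S); Vt <- pca_basis(Tg)
  cs <- colMeans(S); ct <- colMeans(Tg)
  about_centroid <- function(R) rigid_transform(R, ct - as.numeric(R %*% cs))
  cands <- list(identity_transform(), about_centroid(diag(3)))
  for (sg in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
    cands[[length(cands) + 1]] <- about_centroid(Vt %*% diag(sg) %*% t(Vs))
  for (k in 1:3) {
    ax <- c(0, 0, 0); ax[k] <- 1
    for (ang in c(-30, -15, 15, 30) * pi / 180)
      cands[[length(cands) + 1]] <- about_centroid(rodrigues_rotation(ax, ang))
  }
  cands
}

#' Point-to-point iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence search (source points against
#' target vertices) with the closed-form rigid fit until the rms change
#' drops below `convergence_tol` or `max_iterations` is reached. The rms
#' over current correspondences is monotone non-increasing.
#'
#' By default the start is chosen deterministically among the identity and
#' the four proper principal-axes alignments of the two clouds, scored by
#' nearest-neighbour rms: surfaces acquired in a common scanner frame start
#' at (or very near) the identity, while postures repositioned by large
#' placement motions get a pre-alignment that keeps ICP inside the correct
#' basin. Pass an explicit `init` to override.
#'
#' @param source,target Point matrices (n x 3) or `surface_mesh` objects.
#' @param params An [icp_params] object.
#' @param init Optional initial [rigid_transform] applied to the source;
#'   `NULL` (default) selects automatically as described above.
#' @return Object of class `icp_result`: `transform` (maps source onto
#'   target), `rms` (mm), `iterations`, `converged`, `rms_history`.
#' @export
icp_register <- function(source, target, params = icp_params(),
                         init = NULL) {
  S <- as_points(source); Tg <- as_points(target)
  if (!nrow(S) || !nrow(Tg)) stop("empty point set", call. = FALSE)
  stopifnot(inherits(params, "icp_params"))
  S_full <- S
  if (is.finite(params$subsample) && params$subsample < nrow(S)) {
    idx <- with_seed(params$seed, sample.int(nrow(S), params$subsample))
    S <- S[idx, , drop = FALSE]
  }
  if (is.null(init)) {
    # burn in every candidate briefly, then run the most promising few to
    # convergence and keep the lowest final rms; near-symmetric shapes make
    # spurious flipped alignments shallow local minima that only the
    # converged objective separates reliably
    cands <- icp_init_candidates(S_full, Tg)
    burns <- vapply(cands, function(Tc)
      icp_iterate(S, Tg, Tc, max_iter = min(10L, params$max_iterations),
                  tol = params$convergence_tol)$rms, numeric(1))
    top <- order(burns)[seq_len(min(4L, length(cands)))]
    runs <- lapply(cands[top], function(Tc)
      icp_iterate(S, Tg, Tc, max_iter = params$max_iterations,
                  tol = params$convergence_tol))
    run <- runs[[which.min(vapply(runs, `[[`, numeric(1), "rms"))]]
    return(structure(list(transform = run$transform, rms = run$rms,
                          iterations = run$iterations,
                          converged = run$converged,
                          rms_history = run$rms_history),
                     class = "icp_result"))
  }
  run <- icp_iterate(S, Tg, init, max_iter = params$max_iterations,
                     tol = params$convergence_tol)
  structure(list(transform = run$transform, rms = run$rms,
                 iterations = run$iterations, converged = run$converged,
                 rms_history = run$rms_history),
            class = "icp_result")
}

# core ICP loop: alternate NN correspondences and closed-form refit from the
# original source points (so the returned transform is total, and the rms
# over current correspondences never increases)
icp_iterate <- function(S, Tg, T0, max_iter, tol) {
  T_cur <- T0
  rms_prev <- Inf; rms <- Inf
  converged <- FALSE
  iters <- 0L
  rms_history <- numeric(0)
  for (it in seq_len(max_iter)) {
    iters <- it
    S_moved <- apply_transform(T_cur, S)
    nn <- nearest_indices(S_moved, Tg)
    Q <- Tg[nn, , drop = FALSE]
    T_cur <- rigid_fit_correspondences(S, Q)
    S_moved <- apply_transform(T_cur, S)
    rms <- sqrt(mean(rowSums((S_moved - Q)^2)))
    rms_history <- c(rms_history, rms)
    if (abs(rms_prev - rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  list(transform = T_cur, rms = rms, iterations = iters,
       converged = converged, rms_history = rms_history)
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> rms %.4g mm after %d iterations (%s)\n", x$rms,
              x$iterations, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Calcaneus motion between postures, in the talus frame
#'
#' Two-step registration: (1) the other posture's talus is registered to the
#' neutral talus and that alignment is applied to the whole other-posture
#' hindfoot, removing global foot placement; (2) the neutral calcaneus is
#' registered to the talus-aligned other-posture calcaneus. The step-2
#' transform is the calcaneus motion neutral -> other, expressed in the
#' (neutral) talus frame.
#'
#' @param neutral,other Posture entries: lists with elements `talus` and
#'   `calcaneus` (each a `surface_mesh` or point matrix).
#' @param params An [icp_params] object.
#' @return A [rigid_transform] with attributes `talus_rms` and
#'   `calcaneus_rms` (registration rms per step, mm).
#' @export
calcaneus_motion <- function(neutral, other, params = icp_params()) {
  for (p in list(neutral, other))
    if (is.null(p$talus) || is.null(p$calcaneus))
      stop("each posture needs `talus` and `calcaneus` surfaces", call. = FALSE)
  step1 <- icp_register(other$talus, neutral$talus, params)
  if (!step1$converged)
    stop("talus registration did not converge (rms ",
         signif(step1$rms, 3), " mm)", call. = FALSE)
  other_calc_aligned <- apply_transform(step1$transform,
                                        as_points(other$calcaneus))
  step2 <- icp_register(neutral$calcaneus, other_calc_aligned, params)
  if (!step2$converged)
    stop("calcaneus registration did not converge (rms ",
         signif(step2$rms, 3), " mm)", call. = FALSE)
  out <- step2$transform
  attr(out, "talus_rms") <- step1$rms
  attr(out, "calcaneus_rms") <- step2$rms
  out
}
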