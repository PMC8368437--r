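#' LCMV beamformer source reconstruction
#'
#' Computes, for every grid voxel, the scalar linearly constrained
#' minimum-variance (LCMV) spatial filter: the weight vector `w(r)` that
#' minimizes output variance subject to unit gain `w(r)' l(r) = 1`, where
#' `l(r)` is the lead field of the voxel's optimal orientation. The
#' orientation is the generalized-eigenvector solution that maximizes
#' beamformer output power per unit lead-field energy, computed in the
#' non-silent lead-field subspace (the sphere model makes radial moments
#' silent, so each voxel has an effectively 2-D moment space). Voxels whose
#' lead field is numerically zero (e.g. at the sphere centre) are flagged
#' silent and get zero output.
#'
#' @param data A [meg_recording()] or channels x samples matrix
#'   (band-passed segment data).
#' @param leadfield A [sphere_leadfield()] result matching the channels.
#' @param regularization Diagonal loading as a fraction of the mean sensor
#'   variance (default 0.05). With `regularization = 0` the sample
#'   covariance must be well conditioned, which requires at least
#'   2 x channels samples.
#' @return Object of class `meg_source_activity`: list with `Q` (voxels x
#'   samples source time courses), `weights` (voxels x channels),
#'   `orientations` (voxels x 3), `silent` (logical per voxel), `grid`,
#'   `n_timepoints`.
#' @export
beamform <- function(data, leadfield, regularization = 0.05) {
  stopifnot(inherits(leadfield, "meg_leadfield"))
  if (inherits(data, "meg_recording")) data <- data$data
  data <- as.matrix(data)
  nc <- nrow(data); nt <- ncol(data)
  if (nc != dim(leadfield$gains)[1L])
    stop_config("data has %d channels but the lead field expects %d",
                nc, dim(leadfield$gains)[1L])
  if (!is_number(regularization) || regularization < 0)
    stop_config("regularization must be >= 0")
  if (regularization == 0 && nt < 2L * nc)
    stop_config(paste0("segment has %d samples for %d channels; with ",
                       "regularization = 0 at least 2 x channels samples are ",
                       "required -- raise regularization"), nt, nc)
  dm <- data - rowMeans(data)
  C <- tcrossprod(dm) / max(1L, nt - 1L)
  loading <- regularization * mean(diag(C))
  Cr <- C + diag(loading, nc)
  ch <- tryCatch(chol(Cr), error = function(e) NULL)
  if (is.null(ch))
    stop_config(paste0("sensor covariance is singular; raise regularization ",
                       "(current fraction %g)"), regularization)
  Ci <- chol2inv(ch)

  nv <- dim(leadfield$gains)[2L]
  W <- matrix(0, nv, nc)
  ori <- matrix(0, nv, 3L)
  # silence threshold relative to the strongest voxel's lead-field norm
  norm2 <- vapply(seq_len(nv), function(v) sum(leadfield$gains[, v, ]^2), numeric(1L))
  tol2 <- 1e-12 * max(norm2)
  silent <- norm2 <= tol2
  for (v in which(!silent)) {
    L <- leadfield$gains[, v, ]
    N <- crossprod(L)
    eN <- eigen(N, symmetric = TRUE)
    keep <- eN$values > 1e-10 * eN$values[1L]
    U <- eN$vectors[, keep, drop = FALSE]
    CiL <- Ci %*% (L %*% U)
    Mr <- crossprod(L %*% U, CiL)
    Nr <- diag(eN$values[keep], sum(keep))
    # min u' M u s.t. u' N u = 1  <=>  smallest generalized eigenvalue of (M, N)
    S <- Mr / sqrt(outer(eN$values[keep], eN$values[keep]))
    eS <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ured <- eS$vectors[, ncol(eS$vectors)] / sqrt(eN$values[keep])
    u <- as.numeric(U %*% ured)
    u <- u / sqrt(sum(u^2))
    if (u[which.max(abs(u))] < 0) u <- -u        # deterministic sign
    l <- as.numeric(L %*% u)
    Cil <- as.numeric(Ci %*% l)
    denom <- sum(l * Cil)
    W[v, ] <- Cil / denom
    ori[v, ] <- u
  }
  structure(list(Q = W %*% dm, weights = W, orientations = ori,
                 silent = silent, grid = leadfield$grid, n_timepoints = nt),
            class = "meg_source_activity")
}

#' @export
print.meg_source_activity <- function(x, ...) {
  cat(sprintf("<meg_source_activity> %d voxels x %d samples (%d silent voxel(s))\n",
              nrow(x$Q), x$n_timepoints, sum(x$silent)))
  invisible(x)
}
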