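#' Axial angle between two orientations
#'
#' Angle in degrees between two sign-ambiguous (axial) orientations, restricted
#' to \code{[0, 90]}: \code{acos(|u . v|)}. Fixel peaks and streamline segment
#' directions carry no meaningful sign, so a vector and its negation are the
#' same orientation.
#'
#' @param u,v numeric 3-vectors with norm above \code{1e-8} (need not be
#'   exactly unit length; they are normalized internally).
#' @return Angle in degrees in \code{[0, 90]}.
#' @examples
#' axial_angle(c(1, 0, 0), c(0, 1, 0))   # 90
#' axial_angle(c(1, 0, 0), c(-1, 0, 0))  # 0
#' @export
axial_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= 1e-8 || nv <= 1e-8)
    stop("axial_angle: near-zero-norm vector is not a valid orientation")
  acos(min(1, abs(sum(u * v)) / (nu * nv))) * 180 / pi
}

#' Relative fixel contributions to a streamline segment
#'
#' Three strategies distribute a streamline segment's contribution across the
#' fixels of the voxel it traverses. All return a vector of relative
#' contributions \eqn{\alpha_k \in [0,1]} summing to 1 over the present fixels.
#'
#' \describe{
#'   \item{\code{alpha_vol}}{relative volume weighting: \eqn{\alpha_k = f_k /
#'     \sum_{k'} f_{k'}}, independent of the segment orientation.}
#'   \item{\code{alpha_cfo}}{closest-fixel-only: the fixel with the smallest
#'     axial angle to the segment direction receives \eqn{\alpha = 1}; ties are
#'     broken deterministically in favor of the lowest fixel index.}
#'   \item{\code{alpha_ang}}{angular weighting: with \eqn{\theta_k} the axial
#'     angle between the segment and fixel \eqn{k}, and \eqn{\phi = \min(90,
#'     \sum_k \theta_k)}, \eqn{\alpha_k = (\phi - \theta_k) / (\phi K - \sum_k
#'     \theta_k)} for \eqn{K > 1} and \eqn{\alpha = 1} for \eqn{K = 1}. When
#'     the denominator vanishes (all \eqn{\theta_k} equal \eqn{\phi},
#'     including the aligned-fixels case \eqn{\theta \equiv 0}) the continuity
#'     limit \eqn{1/K} is returned.}
#' }
#'
#' @param fractions positive per-fixel volume fractions of the present fixels.
#' @param segment_dir segment direction, a 3-vector (sign irrelevant).
#' @param orientations K x 3 matrix of present fixel orientations.
#' @return Numeric vector of length K summing to 1; \code{numeric(0)} when no
#'   fixel is present (K = 0).
#' @examples
#' alpha_vol(c(0.3, 0.1))                                    # 0.75 0.25
#' alpha_ang(c(1, 0, 0), rbind(c(1, 0, 0), c(0, 1, 0)))      # 1 0
#' @export
alpha_vol <- function(fractions) {
  if (length(fractions) == 0L) return(numeric(0))
  if (any(fractions <= 0)) stop("alpha_vol: present fixels must have fraction > 0")
  fractions / sum(fractions)
}

#' @rdname alpha_vol
#' @export
alpha_cfo <- function(segment_dir, orientations) {
  orientations <- rbind(orientations)
  K <- nrow(orientations)
  if (K == 0L) return(numeric(0))
  theta <- vapply(seq_len(K), function(k) axial_angle(segment_dir, orientations[k, ]),
                  numeric(1))
  a <- numeric(K)
  a[which.min(theta)] <- 1   # which.min takes the first minimum: lowest index wins ties
  a
}

#' @rdname alpha_vol
#' @export
alpha_ang <- function(segment_dir, orientations) {
  orientations <- rbind(orientations)
  K <- nrow(orientations)
  if (K == 0L) return(numeric(0))
  if (K == 1L) {
    axial_angle(segment_dir, orientations[1, ])  # validates inputs
    return(1)
  }
  theta <- vapply(seq_len(K), function(k) axial_angle(segment_dir, orientations[k, ]),
                  numeric(1))
  phi <- min(90, sum(theta))
  den <- phi * K - sum(theta)
  if (den < 1e-12) return(rep(1 / K, K))
  (phi - theta) / den
}

#' Segment-specific microstructural metric
#'
#' The metric value carried by one intra-voxel streamline segment: the
#' contribution-weighted average of the voxel's per-fixel metric values,
#' \eqn{M_{vs} = \sum_k \alpha_k M_k}.
#'
#' @param alphas relative contributions (from \code{\link{alpha_vol}},
#'   \code{\link{alpha_cfo}} or \code{\link{alpha_ang}}).
#' @param metrics per-fixel metric values, same length as \code{alphas}.
#' @return A scalar within \code{[min(metrics), max(metrics)]}, or \code{NA}
#'   when no fixel is present.
#' @export
segment_metric <- function(alphas, metrics) {
  if (length(alphas) == 0L) return(NA_real_)
  if (length(alphas) != length(metrics))
    stop("segment_metric: 'alphas' and 'metrics' lengths differ")
  sum(alphas * metrics)
}

# Strategy dispatch for one voxel-segment configuration.
alpha_for <- function(strategy, segment_dir, orientations, fractions) {
  switch(strategy,
    vol = alpha_vol(fractions),
    cfo = alpha_cfo(segment_dir, orientations),
    ang = alpha_ang(segment_dir, orientations),
    stop("unknown strategy '", strategy, "' (expected one of vol, cfo, ang)")
  )
}

match_strategy <- function(strategy) {
  match.arg(strategy, c("ang", "cfo", "vol"))
}
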