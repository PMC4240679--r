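#' Analysis parameters
#'
#' Bundles the tunable parameters of the resampling/binning procedure.
#'
#' @param P number of expression bins (integer, >= 2). Bin 1 is reserved for
#'   genes receiving no reads in an iteration; nonzero genes are segmented
#'   into bins 2..P.
#' @param I number of resampling iterations (>= 1).
#' @param R reads drawn per iteration: a positive number applied to every
#'   sample, or `"auto"` to use each sample's own mapped-read total.
#' @param seed master seed; all randomness in a run derives from it.
#' @param subsample_step when segmentation is subsampled, fit breakpoints on
#'   every `subsample_step`-th ordered gene.
#' @param subsample_threshold subsample the segmentation input once the number
#'   of genes with nonzero assigned reads exceeds this value.
#' @param dist_threshold \eqn{\delta}: minimum max-norm distance for a DE call,
#'   in (0, 1].
#' @param mode_threshold minimum distance between histogram modes for a DE
#'   call (integer in 0..P-1).
#' @param epsilon tolerance applied to the \eqn{\delta} comparison so that a
#'   distance of 1.0 assembled from I frequency increments still qualifies.
#' @param profile optional named profile applied before the other arguments:
#'   `"phalaris"` (P = 15, I = 100, R = "auto", dist 1.0, mode distance 5) or
#'   `"maqc"` (P = 20, I = 100, R = 1e7).
#' @return an object of class `rodeo_params`.
#' @export
rodeo_params <- function(P = 15, I = 100, R = "auto", seed = 1,
                         subsample_step = 10, subsample_threshold = 2000,
                         dist_threshold = 1.0, mode_threshold = 5,
                         epsilon = 1e-9, profile = NULL) {
  args <- list(P = P, I = I, R = R, seed = seed,
               subsample_step = subsample_step,
               subsample_threshold = subsample_threshold,
               dist_threshold = dist_threshold,
               mode_threshold = mode_threshold, epsilon = epsilon)
  if (!is.null(profile)) {
    prof <- rodeo_profiles()[[match.arg(profile, names(rodeo_profiles()))]]
    supplied <- names(as.list(match.call())[-1])
    for (key in names(prof)) {
      if (!(key %in% supplied)) args[[key]] <- prof[[key]]
    }
  }
  p <- structure(args, class = "rodeo_params")
  validate_params(p)
}

rodeo_profiles <- function() {
  list(
    phalaris = list(P = 15L, I = 100L, R = "auto",
                    dist_threshold = 1.0, mode_threshold = 5L),
    maqc = list(P = 20L, I = 100L, R = 1e7,
                dist_threshold = 1.0, mode_threshold = 5L)
  )
}

validate_params <- function(p) {
  stopifnot(inherits(p, "rodeo_params"))
  if (!is.numeric(p$P) || length(p$P) != 1 || p$P < 2 || p$P != round(p$P))
    stop("P must be a single integer >= 2")
  if (!is.numeric(p$I) || p$I < 1 || p$I != round(p$I))
    stop("I must be a positive integer")
  if (!(identical(p$R, "auto") || (is.numeric(p$R) && length(p$R) == 1 && p$R >= 1)))
    stop("R must be 'auto' or a positive number")
  if (!is.numeric(p$seed) || length(p$seed) != 1)
    stop("seed must be a single number")
  if (!is.numeric(p$subsample_step) || p$subsample_step < 1)
    stop("subsample_step must be a positive integer")
  if (!is.numeric(p$subsample_threshold) || p$subsample_threshold < 1)
    stop("subsample_threshold must be a positive integer")
  if (!is.numeric(p$dist_threshold) || p$dist_threshold <= 0 || p$dist_threshold > 1)
    stop("dist_threshold must lie in (0, 1]")
  if (!is.numeric(p$mode_threshold) || p$mode_threshold < 0 ||
      p$mode_threshold > p$P - 1)
    stop("mode_threshold must be an integer in 0..P-1")
  if (!is.numeric(p$epsilon) || p$epsilon < 0)
    stop("epsilon must be >= 0")
  p$P <- as.integer(p$P); p$I <- as.integer(p$I)
  p$subsample_step <- as.integer(p$subsample_step)
  p$subsample_threshold <- as.integer(p$subsample_threshold)
  p$mode_threshold <- as.integer(p$mode_threshold)
  p
}

#' Read analysis parameters from a YAML config file
#'
#' Recognised keys: `profile`, `P`, `I`, `R`, `seed`, `subsample_step`,
#' `subsample_threshold`, `dist_threshold`, `mode_threshold`, `epsilon`.
#' A `profile` is applied first and individual keys override it.
#'
#' @param path path to a YAML file.
#' @return a [rodeo_params()] object.
#' @export
read_rodeo_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("profile", "P", "I", "R", "seed", "subsample_step",
             "subsample_threshold", "dist_threshold", "mode_threshold",
             "epsilon")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  base <- list()
  if (!is.null(cfg$profile)) {
    base <- rodeo_profiles()[[match.arg(cfg$profile, names(rodeo_profiles()))]]
  }
  for (key in setdiff(names(cfg), "profile")) base[[key]] <- cfg[[key]]
  do.call(rodeo_params, base)
}

#' @export
print.rodeo_params <- function(x, ...) {
  cat("rodeo parameters: P =", x$P, " I =", x$I,
      " R =", if (identical(x$R, "auto")) "auto" else format(x$R),
      " delta =", x$dist_threshold,
      " mode threshold =", x$mode_threshold, "\n")
  invisible(x)
}
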