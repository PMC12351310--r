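#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a master seed
#'
#' Fans a single master seed out to reproducible per-stage seeds by hashing
#' the stage name, so that pipeline stages draw from independent streams
#' without manual seed bookkeeping.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h) %% 2147483647)
}

# evaluate expr under a fixed RNG state without touching the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% 2147483647L, expr)
}

#' Vocalization and non-vocalization category labels
#'
#' The five sound categories of the stimulus set: three macaque
#' vocalizations (coos, screams, aggressive calls) and two non-vocalization
#' controls (other-animal calls and nature sounds).
#'
#' @return Character vector of the five category labels.
#' @export
sound_categories <- function() c("coo", "scream", "aggressive", "animal", "nature")

#' @rdname sound_categories
#' @export
vocal_categories <- function() c("coo", "scream", "aggressive")

#' @rdname sound_categories
#' @export
nonvocal_categories <- function() c("animal", "nature")

# strictly-lower-triangle vectorization shared by the RDM/RSA code
lower_tri_vec <- function(m) m[lower.tri(m)]

# validate a dissimilarity matrix: symmetric, zero diagonal
check_dsm <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("dissimilarity matrix must be square")
  if (max(abs(m - t(m))) > tol) stop("dissimilarity matrix must be symmetric")
  if (max(abs(diag(m))) > tol) stop("dissimilarity matrix must have a zero diagonal")
  invisible(TRUE)
}
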