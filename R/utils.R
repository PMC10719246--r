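#' Derive a reproducible seed for a named random stream
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (per jurisdiction, per dataset variant, per pipeline stage, per ensemble
#' member) are derived by hashing the stream labels together with the root
#' seed, so that e.g. adding jurisdictions to a configuration never perturbs
#' the draws of existing ones.
#'
#' @param root_seed Integer root seed.
#' @param ... Stream labels (coerced to character) identifying the stream.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' stream_seed(1, "jurisdiction", 7, "latent")
stream_seed <- function(root_seed, ...) {
  labels <- paste(c(as.character(root_seed), vapply(list(...), as.character, "")),
                  collapse = "\x1f")
  # 31-bit polynomial rolling hash; 31 * 2^31 < 2^53 so doubles stay exact
  h <- 5381
  for (cp in utf8ToInt(labels)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never disturb
# the user's RNG.
with_stream_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# abort helpers with condition classes so callers can distinguish
# configuration, data, range and fit errors
abort_config <- function(msg) stop(errorCondition(msg, class = c("deforbase_config_error", "deforbase_error")))
abort_data   <- function(msg) stop(errorCondition(msg, class = c("deforbase_data_error", "deforbase_error")))
abort_range  <- function(msg) stop(errorCondition(msg, class = c("deforbase_range_error", "deforbase_error")))
abort_fit    <- function(msg) stop(errorCondition(msg, class = c("deforbase_fit_error", "deforbase_error")))

# sample() without its length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
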