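#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm rbinom rpois runif median quantile setNames
NULL

# Deterministic per-stage seed derived from the master seed, so that adding a
# stage never perturbs another stage's draws. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(name) == 1L)
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(seed) %% 1000003) * 2039 + h) %% 2147483647L
}

# Evaluate `code` under a named substream of `seed`, restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# Weighted mean that returns NA (not NaN) on empty input.
wmean <- function(x, w) {
  keep <- !is.na(x) & !is.na(w)
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Recycle a scalar to a named vector over `nms`, or check names of a vector.
named_over <- function(x, nms, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(nms)), nms))
  }
  if (!all(nms %in% names(x))) {
    abort(sprintf("`%s` must be a scalar or named over: %s",
                  what, paste(nms, collapse = ", ")))
  }
  setNames(as.numeric(x[nms]), nms)
}

TIERS <- c("hospital", "health_centre", "health_post")

MEASURES <- c("readiness_general", "readiness_anc", "readiness_obstetric",
              "readiness_child", "process_anc", "process_obstetric_signal",
              "process_child")

SOURCE_TYPES <- c("public_hospital", "public_health_centre",
                  "public_health_post", "private", "health_hut_or_unknown",
                  "none")

# Facility-type hierarchy used when a woman reports several ANC sources:
# the highest-ranked reported type is assigned.
SOURCE_HIERARCHY <- c("public_hospital", "public_health_centre",
                      "public_health_post", "private")

SERVICES <- c("ANC1", "ANC4", "delivery", "child")
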