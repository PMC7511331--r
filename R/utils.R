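#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rbinom rmultinom runif rgamma median setNames
#'   dbinom kmeans dist
#' @importFrom utils read.delim write.table head
NULL

COMPARTMENTS <- c("epidermis", "dermis", "blood")

# Derive a reproducible sub-seed for a named stage from a master seed.
# Keeps every stream below 2^31 - 1 and decorrelates stages.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 2654435761) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# Zipf-law frequency vector (exponent s) over n ranks, normalised to `mass`.
zipf_frequencies <- function(n, s, mass = 1) {
  if (n == 0L) return(numeric(0))
  w <- seq_len(n)^(-s)
  mass * w / sum(w)
}
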