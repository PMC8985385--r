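#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois rgamma rmultinom pbinom runif quantile
#'   prcomp var sd setNames
#' @importFrom utils adist head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic functions route their
# randomness through this so a seed argument fully determines the output.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# so each pipeline stage is reproducible independently of execution order.
# Kept strictly below 2^31 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 97003) %% 2147483647)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# One draw from Dirichlet(alpha) via normalized gamma variates.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) {
    # numerically degenerate for very small alpha: fall back to picking the
    # single component the limit distribution would choose
    i <- sample.int(length(alpha), 1L, prob = alpha / sum(alpha))
    x <- numeric(length(alpha))
    x[i] <- 1
    return(x)
  }
  x / sum(x)
}

random_dna <- function(n, width, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(alphabet, n * width, replace = TRUE), nrow = width)
  apply(m, 2, paste0, collapse = "")
}

mean_phred <- function(qual_strings) {
  vapply(qual_strings, function(q) {
    if (nchar(q) == 0L) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}
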