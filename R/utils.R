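# Internal helpers: seeding, logging, small validations.

# Run `expr` under a deterministic RNG state without disturbing the
# caller's stream. seed = NULL runs expr as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Named substreams derived from one base seed so that, e.g., changing the
# number of permutations never perturbs the simulated cohort.
.substream <- function(seed, stream) {
  offsets <- c(cohort = 11L, network = 23L, omics = 37L,
               artifacts = 53L, permutation = 71L, masses = 89L)
  if (!stream %in% names(offsets)) {
    stop("unknown RNG substream: ", stream, call. = FALSE)
  }
  (as.integer(seed) * 127L + offsets[[stream]]) %% 2147483587L
}

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

# Lightweight leveled logging to stderr; level filtered through
# options(metlocal.log_level = "INFO").
ml_log <- function(level, ...) {
  threshold <- .log_levels[[toupper(getOption("metlocal.log_level", "INFO"))]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(TRUE)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

# Match a matrix's sample columns against the donor table; returns the
# matrix with columns ordered as in `donors`.
.match_samples <- function(mat, donors, what = "matrix") {
  missing_cols <- setdiff(donors$sample_id, colnames(mat))
  extra_cols <- setdiff(colnames(mat), donors$sample_id)
  if (length(missing_cols) > 0L || length(extra_cols) > 0L) {
    stop(what, " samples do not match the donor table",
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unexpected: ",
                                        paste(extra_cols, collapse = ", ")),
         call. = FALSE)
  }
  mat[, donors$sample_id, drop = FALSE]
}
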