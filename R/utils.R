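# Shared internal helpers.

# 95% CI multiplier, fixed (not recomputed) so printed intervals are stable.
Z95 <- 1.959964

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a numeric scalar argument.
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be supplied", name)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

# Require named columns in a cohort data frame; error names the missing ones.
#' @noRd
check_columns <- function(data, cols, where = "cohort") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stopf("%s is missing required column(s): %s",
          where, paste(missing, collapse = ", "))
  invisible(TRUE)
}

# 32-bit FNV-1a hash of a character scalar; used to stamp outputs with the
# configuration that produced them without pulling in a digest dependency.
#' @noRd
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h %/% 2147483648) * 2147483648
    # 32-bit modular multiply by the FNV prime 16777619, split to stay
    # within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Column-bind a data frame with an optional matrix of extra covariates.
#' @noRd
bind_covariates <- function(df, extra) {
  if (is.null(extra) || NCOL(extra) == 0L) return(df)
  cbind(df, as.data.frame(extra))
}

# Derive a child seed from a master seed; kept below 2^31.
#' @noRd
child_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
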