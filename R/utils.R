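#' @importFrom rlang .data abort warn %||%
#' @importFrom stats coef cor lm median pf pnorm pt qt quantile rbinom rlnorm
#'   rnorm runif sd setNames var
#' @importFrom utils combn read.csv write.csv
NULL

# Metadata columns that identify an animal in a cohort table; everything
# else is treated as a region column.
.meta_cols <- c("animal_id", "sex", "genotype", "treatment", "cohort")

#' Region columns of a cohort table
#'
#' Cohort tables carry one row per animal: identifying metadata columns
#' (`animal_id`, `sex`, `genotype`, `treatment`, optionally `cohort`) plus one
#' numeric column per brain region. This helper returns the region column
#' names in table order.
#'
#' @param data A cohort data frame.
#' @return Character vector of region column names.
#' @export
region_cols <- function(data) {
  setdiff(names(data), .meta_cols)
}

.assert_cohort <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (one row per animal).", call = call)
  }
  regs <- region_cols(data)
  if (length(regs) == 0L) {
    abort("No region columns found: all columns are metadata.", call = call)
  }
  bad <- regs[!vapply(data[regs], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("Non-numeric region columns: ", toString(bad)), call = call)
  }
  na_regs <- regs[vapply(data[regs], anyNA, logical(1))]
  if (length(na_regs) > 0L) {
    abort(paste0("Missing region values in: ", toString(na_regs)), call = call)
  }
  invisible(regs)
}

.check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              call = rlang::caller_env()) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)), call = call)
  }
  invisible(x)
}

# Deterministic per-stage seed derived from a master seed; keeps every
# stage's RNG stream independent while reproducible from one integer.
.derive_seed <- function(seed, stage) {
  offsets <- c(suvr = 101L, pk = 211L, expression = 307L, mrcc = 401L,
               weights = 503L, null = 601L)
  off <- offsets[[stage]] %||% abs(sum(utf8ToInt(stage)))
  (as.integer(seed) * 977L + as.integer(off)) %% 2147483647L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Vectors of community labels of equal length.
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
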