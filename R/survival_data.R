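#' Construct a survival data set for time-to-event genomic analysis
#'
#' Bundles per-individual event/censoring times, failure indicators, optional
#' left-truncation ages and optional fixed covariates. Times are logged once
#' at construction; all model algebra operates on the log scale.
#'
#' @param time positive event or last event-free (censoring) times, in any
#'   consistent unit (typically years of age).
#' @param failure 0/1 failure indicators: 1 if the event was observed at
#'   `time`, 0 if the individual was censored.
#' @param trunc left-truncation ages \eqn{a_i \ge 0}; individuals enter
#'   observation only after surviving to `trunc`. The default 0 disables
#'   truncation, and a zero entry contributes no truncation term to the
#'   likelihood.
#' @param covariates optional numeric matrix or data frame of fixed-effect
#'   covariates (one row per individual). Covariates are z-scored internally
#'   when a model is fitted.
#' @param id optional individual identifiers.
#'
#' @return An object of class `bw_surv`: a list with elements `log_time`,
#'   `failure`, `log_trunc` (`-Inf` where `trunc == 0`), `covariates`,
#'   `time`, `trunc`, `id`, `n`, `d` (number of events).
#' @export
#' @examples
#' sd <- survival_data(time = c(50, 61, 47), failure = c(1, 0, 1))
#' sd$d
survival_data <- function(time, failure, trunc = 0, covariates = NULL,
                          id = NULL) {
  time <- as.numeric(time)
  failure <- as.integer(failure)
  n <- length(time)
  if (length(failure) != n)
    stop("'time' and 'failure' must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be finite and strictly positive before logging")
  if (!all(failure %in% c(0L, 1L)))
    stop("'failure' entries must be 0 or 1")
  trunc <- rep_len(as.numeric(trunc), n)
  if (any(trunc < 0)) stop("left-truncation ages must be >= 0")
  if (any(trunc >= time))
    stop("left-truncation age must be smaller than the recorded time for every individual")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per individual")
    if (any(!is.finite(covariates))) stop("covariates must be finite")
  }
  if (is.null(id)) id <- seq_len(n)
  structure(list(
    log_time = log(time),
    failure = failure,
    log_trunc = ifelse(trunc > 0, log(trunc), -Inf),
    covariates = covariates,
    time = time, trunc = trunc, id = id,
    n = n, d = sum(failure)
  ), class = "bw_surv")
}

#' @export
print.bw_surv <- function(x, ...) {
  cat(sprintf("Survival data: %d individuals, %d events (%.1f%% censored)\n",
              x$n, x$d, 100 * (1 - x$d / x$n)))
  if (any(is.finite(x$log_trunc)))
    cat(sprintf("  left truncation on %d individuals\n",
                sum(is.finite(x$log_trunc))))
  if (!is.null(x$covariates))
    cat(sprintf("  %d covariate(s)\n", ncol(x$covariates)))
  invisible(x)
}

#' Read a phenotype table
#'
#' Whitespace-delimited text with columns `FID IID time failure [trunc_age]`;
#' a header line is optional and detected from the first field. Lines starting
#' with `#` are comments. Times are in original units and logged internally.
#'
#' @param path file path.
#' @return A [survival_data()] object with `id` set to `FID_IID`.
#' @export
read_phenotypes <- function(path) {
  tb <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!is.numeric(tb[[3]])) { # header present
    tb <- read.table(path, header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
  }
  if (ncol(tb) < 4) stop("phenotype file needs columns FID IID time failure")
  trunc <- if (ncol(tb) >= 5) tb[[5]] else 0
  survival_data(time = tb[[3]], failure = tb[[4]], trunc = trunc,
                id = paste(tb[[1]], tb[[2]], sep = "_"))
}

#' Read a covariate table
#'
#' Whitespace-delimited text with columns `FID IID c1 c2 ...`. Returns a
#' numeric matrix with rownames `FID_IID`; covariates are standardised later,
#' at fit time.
#'
#' @param path file path.
#' @export
read_covariates <- function(path) {
  tb <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!is.numeric(tb[[3]])) {
    tb <- read.table(path, header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
  }
  m <- as.matrix(tb[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- paste(tb[[1]], tb[[2]], sep = "_")
  m
}
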