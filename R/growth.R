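# Population-doubling statistics for serial passaging.

#' Population doublings of one passage
#'
#' `M = log2(n_grown / n_seeded)` for a passage that seeded `n_seeded`
#' cells and harvested `n_grown`. Negative values (culture loss) are
#' allowed; a zero harvest yields `-Inf` with the `crashed` attribute set
#' rather than an error, since real cultures can crash.
#'
#' @param n_grown harvested cell count (>= 0).
#' @param n_seeded seeded cell count (> 0); conventionally constant across
#'   passages (e.g. 800,000 cells per 6 cm dish).
#' @return scalar M (vectorized), attribute `crashed` flagging zero
#'   harvests.
#' @examples
#' doublings(3200000, 800000)  # 2 doublings
#' @export
doublings <- function(n_grown, n_seeded) {
  if (any(n_seeded <= 0)) stop("n_seeded must be > 0")
  if (any(n_grown < 0)) stop("n_grown must be >= 0")
  m <- log2(n_grown / n_seeded)
  structure(m, crashed = n_grown == 0)
}

#' Cumulative population-doubling curve over a passage series
#'
#' Per-passage `M` and its running sum (the proliferative-rate curve), plus
#' doublings per day when passage durations are given. No smoothing is
#' applied; raw per-passage values are reported. Gaps in passage numbering
#' warn but do not invalidate the cumulative sum.
#'
#' @param series data.frame with columns `passage`, `n_seeded`, `n_grown`
#'   and optionally `days` (as from [simulate_growth_series()] or
#'   [read_growth_table()]); passage numbers must be strictly increasing.
#' @return data.frame (passage, n_seeded, n_grown, M, cumulative_M, and
#'   `doublings_per_day` when days are present) with attribute `mean_M`.
#' @export
cumulative_doublings <- function(series) {
  if (nrow(series) == 0) {
    out <- data.frame(passage = integer(0), n_seeded = numeric(0),
                      n_grown = numeric(0), M = numeric(0),
                      cumulative_M = numeric(0))
    attr(out, "mean_M") <- NA_real_
    return(out)
  }
  stopifnot(all(c("passage", "n_seeded", "n_grown") %in% names(series)))
  if (is.unsorted(series$passage, strictly = TRUE))
    stop("passage numbers must be strictly increasing")
  if (any(diff(series$passage) > 1))
    warning("gap(s) in passage numbers; cumulative curve still defined")
  m <- doublings(series$n_grown, series$n_seeded)
  out <- data.frame(passage = series$passage, n_seeded = series$n_seeded,
                    n_grown = series$n_grown, M = as.numeric(m),
                    cumulative_M = cumsum(as.numeric(m)))
  if ("days" %in% names(series) && !all(is.na(series$days)))
    out$doublings_per_day <- out$M / series$days
  attr(out, "mean_M") <- mean(out$M)
  attr(out, "crashed") <- attr(m, "crashed")
  out
}

#' Read a passage cell-count CSV
#'
#' @param path CSV with columns line, passage, n_seeded, n_grown and
#'   optionally days.
#' @return data.frame.
#' @export
read_growth_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("passage", "n_seeded", "n_grown")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("growth table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
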