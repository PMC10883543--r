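#' Read and write summary-statistic tables
#'
#' Tab-separated tables with a header row, UTF-8, case-insensitive column
#' names, empty fields as missing.  Expected columns depend on
#' `stat_type` (`z`, `chisq`, `t`, `binom`, `f`, `p`): `z` or
#' `estimate`/`se`; `chisq` and `df`; `estimate`, `se`, `df`; `x`, `n`;
#' `f`, `df1`, `df2`; `p`.  Optional columns `test_id`, `h0`, `h1`
#' (hypothesis spec strings, see [parse_hypothesis()]).
#'
#' @param path File path.
#' @return A data frame with lower-case column names.
#' @export
read_test_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  df
}

#' @rdname read_test_table
#' @param results Data frame of results.
#' @export
write_result_table <- function(results, path) {
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], signif, digits = 15)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Single-test EBFs for a table of summary statistics
#'
#' Dispatches each row to the appropriate family by its `stat_type` and
#' returns one output row per input row.  Rows that cannot be processed
#' are dropped with a warning carrying the row number.
#'
#' @param records Data frame as from [read_test_table()], or a single-row
#'   specification built in code.
#' @param default_h0,default_h1 Hypothesis spec strings used where the
#'   table has no `h0`/`h1` columns.
#' @param alpha Beta prior parameter for binomial rows.
#' @param p_floor Lower clamp for P-value rows (`NULL` to reject
#'   non-positive values).
#' @return Data frame: `test_id`, `stat_type`, `ebf01`, `log10_ebf01`,
#'   `units`, `posterior_prob_h0`, `favoured`, `bias0`, `bias1`.
#' @examples
#' run_single(data.frame(stat_type = "z", z = 1.28))
#' @export
run_single <- function(records, default_h0 = "point:0",
                       default_h1 = "two-sided", alpha = 1, p_floor = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  names(records) <- tolower(names(records))
  if (is.null(records$test_id)) records$test_id <- seq_len(nrow(records))
  out <- lapply(seq_len(nrow(records)), function(i) {
    row <- records[i, , drop = FALSE]
    tryCatch(single_row_ebf(row, default_h0, default_h1, alpha, p_floor),
             error = function(e) {
               warning(sprintf("row %d (%s) skipped: %s", i,
                               row$test_id, conditionMessage(e)),
                       call. = FALSE)
               NULL
             })
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no input row could be processed")
  res
}

single_row_ebf <- function(row, default_h0, default_h1, alpha, p_floor) {
  type <- tolower(as.character(row$stat_type))
  pick <- function(col) if (!is.null(row[[col]]) && !is.na(row[[col]]))
    row[[col]] else NULL
  h0 <- parse_hypothesis(if (!is.null(pick("h0"))) pick("h0") else default_h0)
  h1 <- parse_hypothesis(if (!is.null(pick("h1"))) pick("h1") else default_h1)
  e <- switch(type,
    z = {
      if (!is.null(pick("estimate")))
        ebf_z(estimate = pick("estimate"), se = pick("se"), h0 = h0, h1 = h1)
      else ebf_z(z = pick("z"), h0 = h0, h1 = h1)
    },
    chisq = ebf_z_twosided(sqrt(pick("chisq")), d = pick("df")),
    t = ebf_t(pick("estimate"), pick("se"), pick("df"), h0, h1),
    binom = ebf_binom(pick("x"), pick("n"), h0, h1, alpha = alpha),
    f = ebf_f(pick("f"), pick("df1"), pick("df2"), h0, h1),
    p = ebf_pvalue(pick("p"), floor = p_floor),
    stop("unknown stat_type '", type, "'"))
  data.frame(test_id = row$test_id, stat_type = type,
             ebf01 = e$ebf01, log10_ebf01 = e$log_ebf01 / log(10),
             units = e$units, posterior_prob_h0 = e$posterior_prob_h0,
             favoured = e$favoured, bias0 = e$bias0, bias1 = e$bias1)
}

#' Multiple-testing EBFs for a table of estimates and standard errors
#'
#' Wraps [ebf_multiple()] for tables with `estimate` and `se` columns,
#' preserving input order and adding both single- and multiple-test EBF
#' columns.
#'
#' @inheritParams run_single
#' @param p_theta Common mixture weight.
#' @param h0,h1 Hypothesis spec strings shared by all tests.
#' @return The input data frame plus `ebf01_single`, `ebf01_multiple`,
#'   `log10_ebf10_single`, `log10_ebf10_multiple`.
#' @export
run_multiple <- function(records, p_theta = 1, h0 = "point:0",
                         h1 = "two-sided") {
  stopifnot(is.data.frame(records))
  names(records) <- tolower(names(records))
  if (is.null(records$estimate) || is.null(records$se))
    stop("run_multiple needs 'estimate' and 'se' columns")
  if (any(!is.finite(records$se)) || any(records$se <= 0))
    stop(sprintf("non-positive or missing se in row(s) %s",
                 paste(which(!(records$se > 0)), collapse = ", ")))
  res <- ebf_multiple(records$estimate, records$se,
                      parse_hypothesis(h0), parse_hypothesis(h1),
                      p_theta = p_theta, single = TRUE)
  records$ebf01_single <- res$ebf01_single
  records$ebf01_multiple <- res$ebf01
  records$log10_ebf10_single <- -res$log_ebf01_single / log(10)
  records$log10_ebf10_multiple <- -res$log10_ebf01
  records
}
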