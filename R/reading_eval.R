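#' Read a reading-session sheet
#'
#' CSV with one row per lesion x reader x system:
#' `lesion_id, reader_id, system, detected, suv_max, suv_mean, suv_peak`
#' and an optional `consensus` column that overrides the algorithmic
#' consensus rule.
#'
#' @param path CSV path.
#' @return data frame with normalized types.
#' @export
read_reading_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lesion_id", "reader_id", "system", "detected")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("reading sheet missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$detected <- as.logical(df$detected)
  for (col in c("suv_max", "suv_mean", "suv_peak"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  bad <- !df$detected & (!is.na(df$suv_max) | !is.na(df$suv_mean) |
                           !is.na(df$suv_peak))
  if (any(bad))
    stop("SUV values present for undetected lesions (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  df
}

#' Consensus detection for one lesion on one system
#'
#' Default rule is the conservative logical AND over readers ("detected"
#' only when every reader reported it); an OR rule is available. An
#' externally supplied consensus flag (the readers' discussed agreement)
#' overrides either rule. Consensus SUV is the mean over the readers that
#' reported values.
#'
#' @param detected logical vector, one entry per reader.
#' @param suv optional list/data frame of per-reader SUV triples
#'   (`suv_max`, `suv_mean`, `suv_peak`), NA when not reported.
#' @param rule "and" (default) or "or".
#' @param external optional externally supplied consensus flag.
#' @return list with `detected` and `suv` (triple of means or NAs).
#' @export
consensus <- function(detected, suv = NULL, rule = c("and", "or"),
                      external = NULL) {
  rule <- match.arg(rule)
  if (!length(detected)) stop("at least one reader required", call. = FALSE)
  flag <- if (rule == "and") all(detected) else any(detected)
  if (!is.null(external) && !is.na(external)) {
    if (isTRUE(external) && !any(detected))
      warning("external consensus marks detection but no reader detected",
              call. = FALSE)
    flag <- isTRUE(external)
  }
  triple <- c(suv_max = NA_real_, suv_mean = NA_real_, suv_peak = NA_real_)
  if (flag && !is.null(suv)) {
    for (col in names(triple)) {
      v <- suv[[col]]
      if (!is.null(v) && any(!is.na(v))) triple[col] <- mean(v, na.rm = TRUE)
    }
  }
  list(detected = flag, suv = as.list(triple))
}

#' Union reference standard for natural lesions
#'
#' The set of natural lesions reported by at least one reader on at least
#' one system, deduplicated by lesion id; its size is the natural-lesion
#' denominator for detection rates.
#'
#' @param sheet a reading-sheet data frame (see [read_reading_sheet()])
#'   containing the natural-lesion rows; only rows with `detected == TRUE`
#'   contribute.
#' @return character vector of lesion ids (sorted); length 0 when no
#'   natural lesion was reported.
#' @export
natural_reference <- function(sheet) {
  rep <- sheet$lesion_id[sheet$detected]
  sort(unique(as.character(rep)))
}

#' Build a per-lesion detection table from a reading sheet
#'
#' Applies the consensus rule per lesion x system and returns one row per
#' lesion with per-system consensus flags and consensus SUV triples.
#'
#' @param sheet reading-sheet data frame; `system` must take exactly two
#'   values.
#' @param systems length-2 character, the system labels in (reference,
#'   comparison) order; default the sorted unique values.
#' @param rule consensus rule, "and" or "or".
#' @return a `detection_table` data frame: lesion_id, det_<sys1>,
#'   det_<sys2> plus suv columns per system.
#' @export
detection_table <- function(sheet, systems = NULL, rule = "and") {
  if (is.null(systems)) systems <- sort(unique(sheet$system))
  if (length(systems) != 2L)
    stop("exactly two systems expected", call. = FALSE)
  ids <- unique(sheet$lesion_id)
  rows <- lapply(ids, function(id) {
    out <- list(lesion_id = id)
    for (s in seq_along(systems)) {
      sub <- sheet[sheet$lesion_id == id & sheet$system == systems[s], ,
                   drop = FALSE]
      ext <- if ("consensus" %in% names(sub) && nrow(sub))
        sub$consensus[1] else NULL
      cs <- if (nrow(sub))
        consensus(sub$detected, sub[c("suv_max", "suv_mean", "suv_peak")],
                  rule = rule, external = ext)
      else list(detected = FALSE,
                suv = list(suv_max = NA, suv_mean = NA, suv_peak = NA))
      out[[paste0("det_", s)]] <- cs$detected
      out[[paste0("suv_max_", s)]] <- cs$suv$suv_max
      out[[paste0("suv_mean_", s)]] <- cs$suv$suv_mean
      out[[paste0("suv_peak_", s)]] <- cs$suv$suv_peak
    }
    as.data.frame(out)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "systems") <- systems
  class(tab) <- c("detection_table", class(tab))
  tab
}

#' Detection rate of one system over a lesion table
#'
#' @param table a `detection_table` (or any data frame with `det_1` /
#'   `det_2` logical columns).
#' @param system 1 or 2 (column index) or a system label.
#' @return list with `detected`, `total`, `rate`.
#' @export
detection_rate <- function(table, system = 1) {
  col <- .det_col(table, system)
  det <- table[[col]]
  if (!length(det)) stop("empty lesion table", call. = FALSE)
  list(detected = sum(det), total = length(det), rate = mean(det))
}

.det_col <- function(table, system) {
  if (is.character(system)) {
    systems <- attr(table, "systems")
    m <- match(system, systems)
    if (is.na(m)) stop("unknown system: ", system, call. = FALSE)
    system <- m
  }
  paste0("det_", system)
}

#' Relative true-positive rate (RTPR) between two systems
#'
#' Ratio of the two systems' detection rates on the same lesion set,
#' comparison over reference. The 95\% CI uses the paired asymptotic
#' log-ratio method on the 2x2 cross-classification (variance
#' `(b + c) / (n p1 p2)` where b, c are the discordant counts) when
#' per-lesion pairing is available, and the Katz independent log method
#' otherwise; the method used is recorded in the result.
#'
#' @param table a `detection_table`; `det_2` is the comparison system
#'   (numerator), `det_1` the reference.
#' @param conf confidence level, default 0.95.
#' @param method "paired" (default when pairing available) or "katz".
#' @return an `rtpr_result`: rates, ratio, ci, n, method.
#' @export
rtpr <- function(table, conf = 0.95, method = c("paired", "katz")) {
  method <- match.arg(method)
  d1 <- table$det_1; d2 <- table$det_2
  n <- length(d1)
  x1 <- sum(d1); x2 <- sum(d2)
  rtpr_from_counts(x2, x1, n, n_discordant = sum(d1 != d2),
                   conf = conf,
                   method = if (method == "paired") "paired" else "katz")
}

#' RTPR from detection counts
#'
#' @param x_num detections by the comparison (numerator) system.
#' @param x_den detections by the reference (denominator) system.
#' @param n total lesions (same set for both systems).
#' @param n_discordant number of lesions detected by exactly one system;
#'   required for the paired CI, NULL forces the Katz method.
#' @param conf confidence level.
#' @param method "paired" or "katz".
#' @return an `rtpr_result`.
#' @export
rtpr_from_counts <- function(x_num, x_den, n, n_discordant = NULL,
                             conf = 0.95, method = c("paired", "katz")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  p_num <- x_num / n; p_den <- x_den / n
  if (x_den == 0) {
    res <- list(rate_num = p_num, rate_den = p_den, ratio = Inf,
                ci = c(NA_real_, NA_real_), n = n,
                method = "undefined (reference rate 0)")
    class(res) <- "rtpr_result"
    return(res)
  }
  ratio <- p_num / p_den
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "paired" && is.null(n_discordant)) method <- "katz"
  if (method == "paired" && x_num > 0) {
    # var(log ratio) = (p10 + p01) / (n p1 p2) = (b + c) / (x_num x_den)
    se <- sqrt(n_discordant / (x_num * x_den))
    label <- "paired asymptotic log-ratio"
  } else {
    se <- sqrt(max(0, 1 / x_num - 1 / n + 1 / x_den - 1 / n))
    label <- "Katz independent log-ratio"
  }
  ci <- exp(log(ratio) + c(-1, 1) * z * se)
  res <- list(rate_num = p_num, rate_den = p_den, ratio = ratio,
              ci = ci, n = n, method = label)
  class(res) <- "rtpr_result"
  res
}

#' RTPR from printed detection rates
#' @param rate_num,rate_den detection rates (proportions or percentages).
#' @return the ratio (no CI; counts unavailable).
#' @export
rtpr_from_rates <- function(rate_num, rate_den) {
  if (rate_den <= 0) stop("reference rate must be > 0", call. = FALSE)
  rate_num / rate_den
}

#' @export
print.rtpr_result <- function(x, ...) {
  cat(sprintf("<rtpr> %.2f (95%%CI [%.2f; %.2f]); rates %.3f vs %.3f, n=%d [%s]\n",
              x$ratio, x$ci[1], x$ci[2], x$rate_num, x$rate_den, x$n,
              x$method))
  invisible(x)
}

#' Inter-observer agreement with exact binomial CI
#'
#' Concordance rate between two readers with a Clopper-Pearson exact
#' confidence interval computed from beta quantiles, and a check against
#' the 80\% adequacy threshold.
#'
#' @param n_concordant lesions on which the readers agree.
#' @param n_total total lesions read by both.
#' @param conf confidence level, default 0.95.
#' @param adequacy_threshold IOA considered adequate above this value.
#' @return an `ioa_result`: concordance, ci, n_concordant, n_total,
#'   adequate flag.
#' @export
ioa <- function(n_concordant, n_total, conf = 0.95, adequacy_threshold = 0.8) {
  if (n_total <= 0) stop("n_total must be > 0", call. = FALSE)
  if (n_concordant < 0 || n_concordant > n_total)
    stop("n_concordant must lie in [0, n_total]", call. = FALSE)
  p <- n_concordant / n_total
  a <- (1 - conf) / 2
  lo <- if (n_concordant == 0) 0 else
    stats::qbeta(a, n_concordant, n_total - n_concordant + 1)
  hi <- if (n_concordant == n_total) 1 else
    stats::qbeta(1 - a, n_concordant + 1, n_total - n_concordant)
  res <- list(concordance = p, ci = c(lo, hi),
              n_concordant = n_concordant, n_total = n_total,
              adequate = p > adequacy_threshold)
  class(res) <- "ioa_result"
  res
}

#' @export
print.ioa_result <- function(x, ...) {
  cat(sprintf("<ioa> %.1f%% (95%%CI [%.1f; %.1f]), %d/%d%s\n",
              100 * x$concordance, 100 * x$ci[1], 100 * x$ci[2],
              x$n_concordant, x$n_total,
              if (x$adequate) ", adequate (> 80%)" else ""))
  invisible(x)
}

# paired-detection cell probabilities for the planning model:
# agreement = P(both detect) + P(neither detects); p1 = reference marginal,
# p2 = rtpr * p1 comparison marginal
paired_cells <- function(rtpr_target, agreement, p1) {
  p2 <- rtpr_target * p1
  if (p2 >= 1) stop("rtpr * p1 must be < 1", call. = FALSE)
  # concordance c = 1 - p1 - p2 + 2 p11 is feasible only for
  # |1 - p1 - p2| <= c <= 1 - |p2 - p1|
  if (agreement < abs(1 - p1 - p2) - 1e-12 ||
      agreement > 1 - abs(p2 - p1) + 1e-12)
    stop(sprintf(paste0("infeasible operating point: with rates %.3f and ",
                        "%.3f the agreement must lie in [%.3f, %.3f]"),
                 p1, p2, abs(1 - p1 - p2), 1 - abs(p2 - p1)), call. = FALSE)
  p11 <- (agreement - 1 + p1 + p2) / 2
  p00 <- agreement - p11
  p10 <- p2 - p11   # comparison only
  p01 <- p1 - p11   # reference only
  cells <- c(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
  pmax(cells, 0)
}

# asymptotic power of the two-sided McNemar (discordant z) test at size n
power_mcnemar <- function(n, cells, alpha) {
  psi <- cells["p10"] + cells["p01"]
  d <- cells["p10"] - cells["p01"]
  za <- stats::qnorm(1 - alpha / 2)
  num <- sqrt(n) * abs(d) - za * sqrt(psi)
  den <- sqrt(psi - d^2)
  unname(stats::pnorm(num / den))
}

#' Sample size for a paired comparison of detection rates
#'
#' Smallest number of lesions n such that a two-sided McNemar-type test of
#' equal paired detection rates reaches the requested power against the
#' alternative defined by a target rate ratio, an overall probability of
#' agreement between the two systems (concordant pairs, detected or not)
#' and the reference system's detection rate. The returned n comes from an
#' asymptotic power search seeded by Connor's closed-form approximation.
#'
#' @param rtpr_target alternative detection-rate ratio (> 1).
#' @param agreement probability that the two systems agree on a lesion
#'   (both detect or both miss), in (0, 1).
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power, default 0.80.
#' @param p1 reference-system detection rate under the alternative; the
#'   default `NULL` uses the balanced value `1 / (1 + rtpr_target)` (the
#'   marginals then sum to 1), which keeps every agreement level in
#'   (0, 1 - |p2 - p1|) feasible.
#' @return list with `n`, `power` (asymptotic power at n), `cells` (the
#'   2x2 cell probabilities of the planning model).
#' @export
sample_size_paired <- function(rtpr_target, agreement, alpha = 0.05,
                               power = 0.80, p1 = NULL) {
  if (rtpr_target <= 1) stop("rtpr_target must be > 1", call. = FALSE)
  if (agreement <= 0 || agreement >= 1 || alpha <= 0 || alpha >= 1 ||
      power <= 0 || power >= 1)
    stop("agreement, alpha and power must lie in (0, 1)", call. = FALSE)
  if (is.null(p1)) p1 <- 1 / (1 + rtpr_target)
  cells <- paired_cells(rtpr_target, agreement, p1)
  psi <- cells["p10"] + cells["p01"]
  d <- cells["p10"] - cells["p01"]
  if (d <= 0) stop("infeasible: no detection-rate difference", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(power)
  n0 <- ceiling(unname((za * sqrt(psi) + zb * sqrt(psi - d^2))^2 / d^2))
  n <- max(2L, n0 - 10L)
  while (power_mcnemar(n, cells, alpha) < power) n <- n + 1L
  list(n = n, power = power_mcnemar(n, cells, alpha), cells = cells)
}

#' Monte-Carlo power of the paired detection-rate test
#'
#' Simulates paired reads from the planning model's 2x2 cell
#' probabilities and applies the asymptotic McNemar z test.
#'
#' @param n lesions per group.
#' @param cells named cell probabilities (p11, p10, p01, p00).
#' @param alpha two-sided level.
#' @param n_rep simulation replicates (default 2000).
#' @param seed RNG seed.
#' @return estimated power (rejection proportion).
#' @export
power_paired_mc <- function(n, cells, alpha = 0.05, n_rep = 2000, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  za <- stats::qnorm(1 - alpha / 2)
  draws <- stats::rmultinom(n_rep, n, prob = cells)
  b <- draws[2, ]; c <- draws[3, ]
  disc <- b + c
  z <- ifelse(disc > 0, abs(b - c) / sqrt(disc), 0)
  mean(z > za)
}

#' Inter-observer agreement computed from a reading sheet
#'
#' Concordance between the two readers' detection flags on one system,
#' over all lesions read by both.
#'
#' @param sheet reading-sheet data frame.
#' @param system system label to evaluate.
#' @param conf confidence level.
#' @return an `ioa_result`.
#' @export
ioa_from_sheet <- function(sheet, system, conf = 0.95) {
  sub <- sheet[sheet$system == system, , drop = FALSE]
  readers <- sort(unique(sub$reader_id))
  if (length(readers) != 2L)
    stop("exactly two readers expected, got ", length(readers), call. = FALSE)
  ids <- unique(sub$lesion_id)
  conc <- vapply(ids, function(id) {
    f <- sub$detected[sub$lesion_id == id][order(sub$reader_id[sub$lesion_id == id])]
    length(f) == 2L && f[1] == f[2]
  }, logical(1))
  ioa(sum(conc), length(ids), conf = conf)
}

#' Evaluate a reading sheet into the study's summary statistics
#'
#' Convenience wrapper producing detection rates, RTPR, and RD summaries
#' per SUV metric for the lesions detected on both systems.
#'
#' @param sheet reading-sheet data frame.
#' @param systems length-2 system labels (reference, comparison).
#' @param rule consensus rule.
#' @return list with `table`, `rates`, `rtpr`, `rd` (per metric) —
#'   the evaluation-report shape written by the `report` CLI subcommand.
#' @export
evaluate_reading <- function(sheet, systems = NULL, rule = "and") {
  tab <- detection_table(sheet, systems = systems, rule = rule)
  both <- tab$det_1 & tab$det_2
  rd <- list()
  for (metric in c("suv_max", "suv_mean", "suv_peak")) {
    v1 <- tab[[paste0(metric, "_1")]][both]
    v2 <- tab[[paste0(metric, "_2")]][both]
    ok <- !is.na(v1) & !is.na(v2) & v1 > 0
    rd[[metric]] <- if (any(ok)) summarize_rd(v1[ok], v2[ok]) else NULL
  }
  list(table = tab,
       rates = list(reference = detection_rate(tab, 1),
                    comparison = detection_rate(tab, 2)),
       rtpr = rtpr(tab),
       rd = rd)
}
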