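#' LMS z-score transform
#'
#' Converts a weight into a z-score against an LMS reference triple: the
#' Box-Cox power \code{L}, median \code{M} (grams) and coefficient of
#' variation \code{S}. For \code{L != 0} the transform is
#' \code{z = ((x/M)^L - 1) / (L * S)}; for \code{L = 0} it is the
#' logarithmic limit \code{z = log(x/M) / S}. \code{|L| < 1e-12} is treated
#' as zero.
#'
#' @param weight weight in grams, positive; vectorized.
#' @param L Box-Cox power (dimensionless).
#' @param M reference median in grams, positive.
#' @param S coefficient of variation, positive.
#' @return z-score(s), dimensionless.
#' @seealso [lms_inverse()]
#' @examples
#' lms_zscore(1100, L = 1, M = 1000, S = 0.1) # 1
#' @export
lms_zscore <- function(weight, L, M, S) {
  stopifnot(is.numeric(weight), is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("'weight' must be positive and finite")
  if (any(M <= 0) || any(S <= 0))
    stop("LMS parameters require M > 0 and S > 0")
  r <- weight / M
  ifelse(abs(L) < 1e-12, log(r) / S, (r^L - 1) / (L * S))
}

#' Inverse LMS transform
#'
#' Maps a z-score back to a weight for an LMS triple:
#' \code{x = M * (1 + L*S*z)^(1/L)} for \code{L != 0}, \code{x = M * exp(S*z)}
#' for \code{L = 0}. For \code{L != 0} the argument must satisfy
#' \code{1 + L*S*z > 0} (the invertible range of the Box-Cox transform).
#'
#' @param z z-score(s), dimensionless.
#' @inheritParams lms_zscore
#' @return weight(s) in grams.
#' @export
lms_inverse <- function(z, L, M, S) {
  stopifnot(is.numeric(z), is.numeric(L), is.numeric(M), is.numeric(S))
  if (any(!is.finite(z))) stop("'z' must be finite")
  if (any(M <= 0) || any(S <= 0))
    stop("LMS parameters require M > 0 and S > 0")
  base <- 1 + L * S * z
  bad <- abs(L) >= 1e-12 & base <= 0
  if (any(bad))
    stop("z outside invertible range: 1 + L*S*z must be positive (got ",
         paste(signif(base[bad][1], 4)), ")")
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * base^(1 / L))
}

#' Construct a sex-specific LMS growth chart
#'
#' A growth chart is a table of LMS triples on an increasing postmenstrual-age
#' grid (in days), separately for each sex. Queries at day resolution between
#' grid rows are answered by linear interpolation of L, M and S
#' (see [chart_lookup()]).
#'
#' @param entries data.frame with columns `sex` ("male"/"female"), `pma_days`
#'   (integer postmenstrual age in days), `L`, `M`, `S`.
#' @param name chart label, e.g. "fenton2013" or "synthetic".
#' @return an object of class `growth_chart`.
#' @export
growth_chart <- function(entries, name = "chart") {
  required <- c("sex", "pma_days", "L", "M", "S")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols))
    stop("chart entries lack column(s): ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries)[required]
  entries$sex <- as.character(entries$sex)
  if (!all(entries$sex %in% c("male", "female")))
    stop("chart 'sex' must be 'male' or 'female'")
  if (!all(c("male", "female") %in% entries$sex))
    stop("chart must cover both sexes")
  if (any(!is.finite(entries$pma_days)) || any(entries$pma_days < 22 * 7))
    stop("chart 'pma_days' must be finite and >= 154 (22 weeks)")
  if (any(entries$M <= 0) || any(entries$S <= 0))
    stop("chart requires M > 0 and S > 0 in every row")
  entries <- entries[order(entries$sex, entries$pma_days), , drop = FALSE]
  rownames(entries) <- NULL
  for (sx in c("male", "female")) {
    age <- entries$pma_days[entries$sex == sx]
    if (length(age) < 2L)
      stop("chart needs at least two age rows for sex '", sx, "'")
    if (any(diff(age) <= 0))
      stop("chart 'pma_days' must be strictly increasing for sex '", sx, "'")
    if (any(diff(entries$M[entries$sex == sx]) < 0))
      warning("chart median M is not non-decreasing in age for sex '", sx, "'")
  }
  structure(list(name = name, entries = entries), class = "growth_chart")
}

#' @export
print.growth_chart <- function(x, ...) {
  rng <- range(x$entries$pma_days)
  cat("<growth_chart> ", x$name, ": ", nrow(x$entries), " LMS rows, PMA ",
      rng[1], "-", rng[2], " days (", round(rng[1] / 7, 1), "-",
      round(rng[2] / 7, 1), " wk), both sexes\n", sep = "")
  invisible(x)
}

#' Look up (interpolated) LMS parameters at a given age
#'
#' Returns the chart's L, M and S for one sex at postmenstrual ages given in
#' days. Ages on the stored grid return the stored row; ages between grid rows
#' are linearly interpolated in each of L, M, S independently. Ages outside
#' the grid are a hard error (extrapolated reference values are clinically
#' meaningless).
#'
#' @param chart a [growth_chart()].
#' @param sex "male" or "female" (scalar or vector matching `pma_days`).
#' @param pma_days postmenstrual age(s) in days.
#' @return data.frame with columns `L`, `M`, `S`, one row per query.
#' @export
chart_lookup <- function(chart, sex, pma_days) {
  stopifnot(inherits(chart, "growth_chart"))
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("unknown sex: ", paste(unique(setdiff(sex, c("male", "female"))),
                                collapse = ", "))
  n <- max(length(sex), length(pma_days))
  sex <- rep_len(sex, n)
  pma_days <- rep_len(as.numeric(pma_days), n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (sx in unique(sex)) {
    idx <- which(sex == sx)
    e <- chart$entries[chart$entries$sex == sx, , drop = FALSE]
    lo <- min(e$pma_days); hi <- max(e$pma_days)
    bad <- pma_days[idx] < lo | pma_days[idx] > hi
    if (any(bad))
      stop("postmenstrual age ", paste(pma_days[idx][bad][1]),
           " days outside chart '", chart$name, "' range [", lo, ", ", hi,
           "] days for sex '", sx, "'")
    for (p in c("L", "M", "S"))
      out[[p]][idx] <- stats::approx(e$pma_days, e[[p]], xout = pma_days[idx],
                                     method = "linear", ties = "ordered")$y
  }
  out
}

#' Weight z-score against a growth chart
#'
#' Convenience wrapper: interpolates the chart at the requested age(s) and
#' applies [lms_zscore()].
#'
#' @inheritParams chart_lookup
#' @param weight weight(s) in grams.
#' @return z-score vector.
#' @export
chart_zscore <- function(chart, sex, pma_days, weight) {
  p <- chart_lookup(chart, sex, pma_days)
  lms_zscore(weight, p$L, p$M, p$S)
}

#' Read a growth-chart CSV
#'
#' Expects the dialect `sex,pma_weeks,L,M,S` with sex in \{male, female\} and
#' `pma_weeks` in decimal weeks (converted to days by multiplying by 7 and
#' rounding to the nearest day). Malformed files are rejected with
#' line-numbered messages (line 1 is the header).
#'
#' @param path CSV file path.
#' @param name chart label; defaults to the file name without extension.
#' @return a [growth_chart()].
#' @export
read_growth_chart <- function(path, name = NULL) {
  if (!file.exists(path)) stop("chart file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  want <- c("sex", "pma_weeks", "L", "M", "S")
  if (!identical(names(raw), want))
    stop("line 1: chart header must be '", paste(want, collapse = ","),
         "' (got '", paste(names(raw), collapse = ","), "')")
  if (nrow(raw) == 0L) stop("chart file has no data rows: ", path)
  problems <- character(0)
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  pma <- num("pma_weeks"); L <- num("L"); M <- num("M"); S <- num("S")
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L
    if (!raw$sex[i] %in% c("male", "female"))
      problems <- c(problems, paste0("line ", line, ": sex must be male or female"))
    if (is.na(pma[i]) || pma[i] <= 0)
      problems <- c(problems, paste0("line ", line, ": pma_weeks must be a positive number"))
    if (is.na(L[i]))
      problems <- c(problems, paste0("line ", line, ": L must be numeric"))
    if (is.na(M[i]) || M[i] <= 0)
      problems <- c(problems, paste0("line ", line, ": M must be a positive number"))
    if (is.na(S[i]) || S[i] <= 0)
      problems <- c(problems, paste0("line ", line, ": S must be a positive number"))
  }
  if (length(problems))
    stop("invalid chart file ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  growth_chart(data.frame(sex = raw$sex, pma_days = round(pma * 7),
                          L = L, M = M, S = S), name = name)
}

#' Write a growth chart to CSV
#'
#' Emits the `sex,pma_weeks,L,M,S` dialect read by [read_growth_chart()].
#'
#' @param chart a [growth_chart()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_chart <- function(chart, path) {
  stopifnot(inherits(chart, "growth_chart"))
  e <- chart$entries
  out <- data.frame(sex = e$sex, pma_weeks = e$pma_days / 7,
                    L = e$L, M = e$M, S = e$S)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
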