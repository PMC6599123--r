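#' Read a cohort CSV
#'
#' Expects the dialect `id,sex,ga_days,birth_weight,discharge_weight,stay_days`
#' with optional extra covariate columns (empty fields allowed there). Rows
#' with a missing or invalid core field are rejected, not repaired: the
#' returned data.frame carries only valid rows, and the rejected rows with
#' line-numbered reasons are attached as attribute `"rejected"` and reported
#' via [message()].
#'
#' Validity: sex in \{male, female\}; gestational age in [154, 231) days
#' (22 to <33 completed weeks); both weights positive; stay at least 1 day.
#'
#' @param path CSV file path.
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  core <- c("id", "sex", "ga_days", "birth_weight", "discharge_weight",
            "stay_days")
  missing_cols <- setdiff(core, names(raw))
  if (length(missing_cols))
    stop("line 1: cohort header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("cohort file has no data rows: ", path)
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  ga <- num("ga_days"); bw <- num("birth_weight")
  dw <- num("discharge_weight"); st <- num("stay_days")
  reasons <- character(nrow(raw))
  add <- function(reasons, bad, why)
    ifelse(bad, ifelse(nzchar(reasons), paste(reasons, why, sep = "; "), why),
           reasons)
  reasons <- add(reasons, !raw$sex %in% c("male", "female"),
                 "sex must be male or female")
  reasons <- add(reasons, is.na(ga) | ga < 22 * 7 | ga >= 33 * 7,
                 "ga_days must be in [154, 231)")
  reasons <- add(reasons, is.na(bw) | bw <= 0,
                 "birth_weight must be a positive number")
  reasons <- add(reasons, is.na(dw) | dw <= 0,
                 "discharge_weight must be a positive number")
  reasons <- add(reasons, is.na(st) | st < 1, "stay_days must be >= 1")
  bad <- nzchar(reasons)
  cohort <- data.frame(id = raw$id, sex = raw$sex, ga_days = ga,
                       birth_weight = bw, discharge_weight = dw,
                       stay_days = st)
  extra <- setdiff(names(raw), core)
  for (cn in extra) cohort[[cn]] <- raw[[cn]]
  rejected <- data.frame(line = which(bad) + 1L, id = raw$id[bad],
                         reason = reasons[bad], row.names = NULL)
  if (any(bad))
    message(sum(bad), " of ", nrow(raw), " cohort row(s) rejected (see ",
            "attr(x, 'rejected')); first: line ", rejected$line[1], ": ",
            rejected$reason[1])
  cohort <- cohort[!bad, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("no valid cohort rows in ", path)
  rownames(cohort) <- NULL
  attr(cohort, "rejected") <- rejected
  cohort
}

#' Write a cohort CSV
#'
#' Emits the dialect read by [read_cohort()].
#'
#' @param cohort cohort data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
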