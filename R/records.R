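#' Observed scores for one subject
#'
#' Bundles a subject's occasion schedule, 4 x K score matrix (words recalled
#' on the three immediate and one delayed recall trial; `NA` marks missing
#' trials), diagnosis group and covariates.
#'
#' @param subject_id character or numeric identifier.
#' @param times strictly increasing occasion times (years since baseline).
#' @param scores 4 x K numeric matrix (rows = trials 1-4); at least one
#'   entry must be observed.
#' @param group one of `"CU"`, `"MCI"`, `"DAT"` (cognitively unimpaired,
#'   mild cognitive impairment, dementia of the Alzheimer's type).
#' @param age baseline age in years.
#' @param sex coded -1 for men, +1 for women.
#' @param education years of education.
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(subject_id, times, scores, group,
                           age = NA_real_, sex = NA_real_,
                           education = NA_real_) {
  validate_schedule(times)
  scores <- as.matrix(scores)
  if (nrow(scores) != 4L || ncol(scores) != length(times)) {
    stop("scores must be a 4 x K matrix matching the schedule length")
  }
  if (all(is.na(scores))) stop("at least one score must be observed")
  if (!all(is.finite(scores[!is.na(scores)]))) {
    stop("observed scores must be finite")
  }
  group <- match.arg(group, c("CU", "MCI", "DAT"))
  dimnames(scores) <- list(paste0("trial", 1:4), NULL)
  structure(
    list(subject_id = as.character(subject_id), times = as.numeric(times),
         scores = scores, group = group, age = age, sex = sex,
         education = education),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("subject %s (%s), %d occasion(s) over %.2f years\n",
              x$subject_id, x$group, length(x$times), max(x$times)))
  print(round(x$scores, 2))
  invisible(x)
}

new_cohort <- function(records, manifest = NULL) {
  structure(records, class = "pe_cohort", manifest = manifest)
}

#' @export
print.pe_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("synthetic cohort: %d subjects (%s)\n", length(x),
              paste(sprintf("%s %d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Read and write cohorts as long-format CSV
#'
#' One row per subject-occasion with columns `subject_id`, `time_years`,
#' `trial1`..`trial4`, `group`, `age`, `sex`, `education`. Missing trial
#' scores are empty cells; the dialect is RFC-4180, UTF-8, `.` decimal.
#'
#' @param path file path.
#' @param records a list of [subject_record()] objects (or a cohort from
#'   [generate_cohort()]).
#' @return `read_cohort_csv()` returns a cohort (list of subject records);
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years", paste0("trial", 1:4), "group",
            "age", "sex", "education")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  records <- lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_years), , drop = FALSE]
    subject_record(
      subject_id = id,
      times = rows$time_years,
      scores = t(as.matrix(rows[, paste0("trial", 1:4)])),
      group = rows$group[1L],
      age = rows$age[1L], sex = rows$sex[1L], education = rows$education[1L]
    )
  })
  new_cohort(records)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      subject_id = r$subject_id,
      time_years = r$times,
      trial1 = r$scores[1L, ], trial2 = r$scores[2L, ],
      trial3 = r$scores[3L, ], trial4 = r$scores[4L, ],
      group = r$group, age = r$age, sex = r$sex, education = r$education,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
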