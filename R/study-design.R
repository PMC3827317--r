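#' Sample design table for a paired two-arm study
#'
#' Validates the per-sample metadata of a paired pre/post (t0/t4) design
#' with a placebo and an etanercept arm. Arm and timepoint tokens are
#' case-normalized to lower case.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `arm`
#'   (placebo | etanercept) and `timepoint` (t0 | t4).
#' @return A `study_design`: the validated data.frame (character columns,
#'   row order preserved).
#' @export
study_design <- function(df) {
  need <- c("sample_id", "subject_id", "arm", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(lapply(df[need], as.character), stringsAsFactors = FALSE)
  df$arm <- tolower(df$arm)
  df$timepoint <- tolower(df$timepoint)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$arm), c("placebo", "etanercept"))
  if (length(bad))
    stop("unknown arm token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$timepoint), c("t0", "t4"))
  if (length(bad))
    stop("unknown timepoint token(s): ", paste(bad, collapse = ", "))
  key <- paste(df$subject_id, df$timepoint)
  dup <- unique(df$subject_id[duplicated(key)])
  if (length(dup))
    stop("subject(s) with two samples at one timepoint: ",
         paste(dup, collapse = ", "))
  arms_per_subject <- tapply(df$arm, df$subject_id,
                             function(a) length(unique(a)))
  bad <- names(arms_per_subject)[arms_per_subject > 1]
  if (length(bad))
    stop("subject(s) present in both arms: ", paste(bad, collapse = ", "))
  class(df) <- c("study_design", "data.frame")
  df
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d subjects (%s)\n",
              nrow(x), length(unique(x$subject_id)),
              paste(names(table(x$arm)), table(x$arm),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Complete pre/post sample pairs of one arm
#'
#' @param design a [study_design()]
#' @param arm `"placebo"` or `"etanercept"`
#' @return data.frame with one row per subject having both timepoints:
#'   columns `subject_id`, `t0`, `t4` (sample ids).
#' @export
complete_pairs <- function(design, arm = c("placebo", "etanercept")) {
  arm <- match.arg(arm)
  d <- design[design$arm == arm, , drop = FALSE]
  t0 <- d[d$timepoint == "t0", c("subject_id", "sample_id")]
  t4 <- d[d$timepoint == "t4", c("subject_id", "sample_id")]
  subjects <- intersect(t0$subject_id, t4$subject_id)
  # keep the arm's subject order
  subjects <- unique(d$subject_id)[unique(d$subject_id) %in% subjects]
  data.frame(subject_id = subjects,
             t0 = t0$sample_id[match(subjects, t0$subject_id)],
             t4 = t4$sample_id[match(subjects, t4$subject_id)],
             stringsAsFactors = FALSE)
}
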