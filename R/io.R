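#' Read and write the tabular interchange formats
#'
#' TAC files are TSV with columns `frame_start_min`, `frame_duration_min`,
#' `activity_kBq_per_mL`; blood files are TSV with columns `time_min`,
#' `wholeblood_kBq_per_mL`, `plasma_over_blood`, `parent_fraction`
#' (`NA` where a modality was not sampled).
#'
#' @param path file path.
#' @return `read_tac_tsv()`: list with `schedule` ([frame_schedule()]) and
#'   `tac`; `read_blood_tsv()`: the blood data.frame.
#' @name tac_io
NULL

#' @rdname tac_io
#' @export
read_tac_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t")
  need <- c("frame_start_min", "frame_duration_min", "activity_kBq_per_mL")
  if (!all(need %in% names(d))) {
    stop("TAC file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  list(schedule = frame_schedule(d$frame_start_min, d$frame_duration_min),
       tac = d$activity_kBq_per_mL)
}

#' @rdname tac_io
#' @param schedule a [frame_schedule()].
#' @param tac frame activities.
#' @export
write_tac_tsv <- function(schedule, tac, path) {
  utils::write.table(
    data.frame(frame_start_min = schedule$start,
               frame_duration_min = schedule$duration,
               activity_kBq_per_mL = tac),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tac_io
#' @export
read_blood_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t")
  need <- c("time_min", "wholeblood_kBq_per_mL", "plasma_over_blood",
            "parent_fraction")
  if (!all(need %in% names(d))) {
    stop("blood file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d
}

#' @rdname tac_io
#' @param blood blood data.frame as from [generate_input_function()].
#' @export
write_blood_tsv <- function(blood, path) {
  utils::write.table(blood, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
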