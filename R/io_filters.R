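#' Read test-day records
#'
#' Expects a CSV with header
#' `animal_id,herd_id,test_date,calving_date,birth_date,dim,my,fp,pp,bcs`,
#' ISO-8601 dates and empty cells for missing trait values (sentinel numbers
#' are not accepted: a numeric cell is taken at face value and range-checked).
#'
#' @param path CSV file path.
#' @return data frame of typed records; missing traits are `NA`.
#' @export
read_records <- function(path) {
  cols <- c(animal_id = "character", herd_id = "character",
            test_date = "character", calving_date = "character",
            birth_date = "character", dim = "integer", my = "numeric",
            fp = "numeric", pp = "numeric", bcs = "integer")
  df <- tryCatch(
    read.csv(path, colClasses = unname(cols), strip.white = TRUE),
    error = function(e) stop("malformed records file '", path, "': ",
                             conditionMessage(e))
  )
  if (!identical(names(df), names(cols))) {
    stop("records file must have header ",
         paste(names(cols), collapse = ","))
  }
  for (dc in c("test_date", "calving_date", "birth_date")) {
    d <- as.Date(df[[dc]], format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df[[dc]]) & nzchar(df[[dc]]))
    if (length(bad)) {
      stop("malformed ", dc, " at data line ", bad[1], " of '", path, "'")
    }
    df[[dc]] <- d
  }
  validate_records(df)
  df
}

#' Validate test-day record invariants
#'
#' Checks the structural invariants every record set must satisfy: positive
#' DIM, BCS (when present) on the 1-9 integer scale, test date after calving
#' date, and at most one record per animal and test date.
#'
#' @param records data frame of records.
#' @return invisibly, the records.
#' @export
validate_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$dim < 1, na.rm = TRUE)) {
    stop("dim must be >= 1 (line ", which(records$dim < 1)[1], ")")
  }
  bad_bcs <- which(!is.na(records$bcs) &
                   (records$bcs < 1 | records$bcs > 9))
  if (length(bad_bcs)) {
    stop("bcs outside the 1-9 scale at data line ", bad_bcs[1])
  }
  bad_date <- which(!is.na(records$test_date) & !is.na(records$calving_date) &
                    records$test_date <= records$calving_date)
  if (length(bad_date)) {
    stop("test_date not after calving_date at data line ", bad_date[1])
  }
  key <- paste(records$animal_id, records$test_date)
  if (anyDuplicated(key)) {
    stop("duplicate animal x test_date record: ",
         key[duplicated(key)][1])
  }
  invisible(records)
}

#' Write test-day records
#' @param records data frame of records.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_records <- function(records, path) {
  out <- records[, c("animal_id", "herd_id", "test_date", "calving_date",
                     "birth_date", "dim", "my", "fp", "pp", "bcs")]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the standard data edits
#'
#' Edits, in a fixed order, then iterated to a fixed point:
#' \enumerate{
#'   \item trait ranges: milk yield 3-70 kg, fat 1-9 \%, protein 1-7 \%
#'     (out-of-range values drop the record);
#'   \item days in milk restricted to 5-365;
#'   \item age at first calving (calving minus birth date, integer days)
#'     restricted to 540-1200 days, bounds inclusive;
#'   \item cows must have at least two test-day records with complete milk
#'     traits and at least two BCS records;
#'   \item herds with fewer than 10 surviving cows are removed.
#' }
#' Removing a herd can push a cow below the minimum-test rule and vice versa,
#' so rules 4-5 are re-applied until nothing changes. Attrition is reported
#' per rule in application order.
#'
#' @param records data frame of records (see [read_records()]).
#' @return list with `records` (the survivors) and `report` (a
#'   `filter_report` data frame of per-rule record drops).
#' @export
apply_edits <- function(records) {
  n0 <- nrow(records)
  drops <- list()
  keep <- records

  in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  ok <- in_range(keep$my, 3, 70) & in_range(keep$fp, 1, 9) &
    in_range(keep$pp, 1, 7)
  drops$trait_range <- sum(!ok)
  keep <- keep[ok, , drop = FALSE]

  ok <- keep$dim >= 5L & keep$dim <= 365L
  drops$dim_window <- sum(!ok)
  keep <- keep[ok, , drop = FALSE]

  age <- as.integer(as.Date(keep$calving_date) - as.Date(keep$birth_date))
  ok <- age >= 540L & age <= 1200L
  drops$age_window <- sum(!ok)
  keep <- keep[ok, , drop = FALSE]

  drops$min_tests_per_cow <- 0L
  drops$min_herd_size <- 0L
  repeat {
    n_milk <- table(keep$animal_id)
    n_bcs <- table(keep$animal_id[!is.na(keep$bcs)])
    good_cows <- names(n_milk)[n_milk >= 2L]
    good_cows <- intersect(good_cows, names(n_bcs)[n_bcs >= 2L])
    ok <- keep$animal_id %in% good_cows
    drops$min_tests_per_cow <- drops$min_tests_per_cow + sum(!ok)
    keep <- keep[ok, , drop = FALSE]

    cows_per_herd <- tapply(keep$animal_id, keep$herd_id,
                            function(a) length(unique(a)))
    good_herds <- names(cows_per_herd)[cows_per_herd >= 10L]
    ok2 <- keep$herd_id %in% good_herds
    drops$min_herd_size <- drops$min_herd_size + sum(!ok2)
    keep <- keep[ok2, , drop = FALSE]
    if (all(ok) && all(ok2)) break
  }

  report <- data.frame(
    rule = c("trait_range", "dim_window", "age_window",
             "min_tests_per_cow", "min_herd_size", "surviving"),
    records = c(unlist(drops[c("trait_range", "dim_window", "age_window",
                               "min_tests_per_cow", "min_herd_size")]),
                nrow(keep)),
    row.names = NULL
  )
  class(report) <- c("filter_report", class(report))
  stopifnot(sum(report$records) == n0)
  rownames(keep) <- NULL
  list(records = keep, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("Record attrition (rules in application order):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %8d\n", x$rule[i], x$records[i]))
  }
  invisible(x)
}

#' Read a run configuration
#'
#' YAML key/value file with sections naming paths, seeds and model settings.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a run configuration
#' @param config named list.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
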