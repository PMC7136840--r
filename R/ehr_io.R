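# Reading, validating and encoding longitudinal EHR event tables.
#
# An event table has one row per clinical event with columns
# patient_id, encounter_id, timestamp, view, code, abnormal_flag, mortality.
# Views are the three clinical feature families: diagnosis (ICD) codes,
# medications and laboratory components (with an abnormal flag).

#' Declare the dialect of an event table
#'
#' @param format one of `"csv"`, `"tsv"`, `"jsonl"`.
#' @param timestamp_format a [base::strptime()] date format string.
#' @param columns named character vector mapping the standard column names
#'   (`patient_id`, `encounter_id`, `timestamp`, `view`, `code`,
#'   `abnormal_flag`, `mortality`) to the column names used in the file.
#' @return an object of class `event_dialect`.
#' @export
event_dialect <- function(format = c("csv", "tsv", "jsonl"),
                          timestamp_format = "%Y-%m-%d",
                          columns = NULL) {
  format <- match.arg(format)
  std <- c("patient_id", "encounter_id", "timestamp", "view", "code",
           "abnormal_flag", "mortality")
  cols <- stats::setNames(std, std)
  if (!is.null(columns)) {
    stopifnot(all(names(columns) %in% std))
    cols[names(columns)] <- columns
  }
  structure(list(format = format, timestamp_format = timestamp_format,
                 columns = cols),
            class = "event_dialect")
}

#' Load a longitudinal EHR event table
#'
#' Parses a delimited-text or JSON-lines event table. Rows whose timestamp
#' cannot be parsed under the declared format, whose code is empty, or whose
#' mortality label is not 0/1 are collected as structured rejections rather
#' than aborting the load; a missing mandatory column is a hard failure.
#'
#' @param path file path.
#' @param dialect an [event_dialect()].
#' @return a list of class `event_table` with elements `events` (a data frame
#'   of parsed clinical events, row order preserved) and `rejections` (a data
#'   frame with `line` and `reason`).
#' @export
load_event_table <- function(path, dialect = event_dialect()) {
  stopifnot(file.exists(path))
  raw <- switch(dialect$format,
    csv  = utils::read.csv(path, colClasses = "character", check.names = FALSE),
    tsv  = utils::read.delim(path, colClasses = "character", check.names = FALSE),
    jsonl = {
      con <- file(path, open = "r")
      on.exit(close(con))
      df <- jsonlite::stream_in(con, verbose = FALSE)
      df[] <- lapply(df, as.character)
      df
    })
  cols <- dialect$columns
  mandatory <- setdiff(names(cols), "abnormal_flag")
  missing <- mandatory[!cols[mandatory] %in% names(raw)]
  if (length(missing) > 0) {
    stop("event table is missing mandatory column(s): ",
         paste(cols[missing], collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0) {
    return(structure(list(events = empty_events(), rejections = empty_rejections()),
                     class = "event_table"))
  }
  get_col <- function(std) {
    if (cols[[std]] %in% names(raw)) raw[[cols[[std]]]] else rep(NA_character_, n)
  }
  ts <- as.Date(get_col("timestamp"), format = dialect$timestamp_format)
  code <- get_col("code")
  mort_raw <- get_col("mortality")
  mort <- suppressWarnings(as.integer(mort_raw))
  flag_raw <- tolower(trimws(get_col("abnormal_flag")))
  flag <- rep(NA, n)
  flag[flag_raw %in% c("true", "t", "1", "yes")] <- TRUE
  flag[flag_raw %in% c("false", "f", "0", "no")] <- FALSE

  reasons <- character(n)
  bad_ts <- is.na(ts)
  reasons[bad_ts] <- "unparseable timestamp"
  bad_code <- !bad_ts & (is.na(code) | !nzchar(trimws(code)))
  reasons[bad_code] <- "empty code"
  bad_mort <- !bad_ts & !bad_code & (is.na(mort) | !mort %in% c(0L, 1L))
  reasons[bad_mort] <- "invalid mortality label"
  bad <- nzchar(reasons)

  events <- data.frame(
    patient_id   = get_col("patient_id"),
    encounter_id = get_col("encounter_id"),
    timestamp    = ts,
    view         = get_col("view"),
    code         = trimws(code),
    abnormal_flag = flag,
    mortality    = mort,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  rownames(events) <- NULL
  rejections <- data.frame(line = which(bad) + 1L,  # +1 for the header row
                           reason = reasons[bad], stringsAsFactors = FALSE)
  structure(list(events = events, rejections = rejections),
            class = "event_table")
}

empty_events <- function() {
  data.frame(patient_id = character(), encounter_id = character(),
             timestamp = as.Date(character()), view = character(),
             code = character(), abnormal_flag = logical(),
             mortality = integer(), stringsAsFactors = FALSE)
}

empty_rejections <- function() {
  data.frame(line = integer(), reason = character(), stringsAsFactors = FALSE)
}

#' Write an event table to delimited text
#'
#' @param events a data frame of clinical events (as in
#'   [load_event_table()]`$events`).
#' @param path output file path.
#' @param dialect an [event_dialect()]; only `"csv"` and `"tsv"` are supported.
#' @export
write_event_table <- function(events, path, dialect = event_dialect()) {
  out <- events
  out$timestamp <- format(out$timestamp, dialect$timestamp_format)
  sep <- switch(dialect$format, csv = ",", tsv = "\t",
                stop("write_event_table supports csv/tsv only"))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Build a cohort of patient timelines from clinical events
#'
#' Applies the cohort rules: events are grouped into encounters per patient,
#' encounters are ordered chronologically (ties broken by encounter id), and
#' patients with fewer than two encounters are excluded (and counted). In
#' abnormal-only mode (the default, matching the best-performing
#' configuration), laboratory codes contribute an indicator only when flagged
#' abnormal.
#'
#' @param events an `event_table` or its `events` data frame.
#' @param abnormal_only logical; keep only abnormal laboratory components.
#' @return a list of `patient_timeline` objects of class `ehr_cohort`, with
#'   attributes `n_excluded` (patients dropped by the two-encounter rule) and
#'   `abnormal_only`.
#' @export
build_cohort <- function(events, abnormal_only = TRUE) {
  if (inherits(events, "event_table")) events <- events$events
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    return(structure(list(), class = "ehr_cohort", n_excluded = 0L,
                     abnormal_only = abnormal_only))
  }
  unknown <- setdiff(unique(events$view), .views)
  if (length(unknown) > 0) {
    stop("unknown view tag(s): ", paste(unknown, collapse = ", "))
  }
  lab_rows <- events$view == "lab"
  if (any(lab_rows & is.na(events$abnormal_flag))) {
    stop("lab events must carry an abnormal_flag")
  }

  split_events <- split(events, events$patient_id)
  n_excluded <- 0L
  timelines <- list()
  for (pid in names(split_events)) {
    ev <- split_events[[pid]]
    mort <- unique(ev$mortality)
    if (length(mort) != 1) {
      stop("conflicting mortality labels for patient ", pid)
    }
    enc_ids <- unique(ev$encounter_id)
    # encounter timestamp = earliest event timestamp within the encounter
    enc_ts <- as.Date(vapply(enc_ids, function(e) {
      min(ev$timestamp[ev$encounter_id == e])
    }, numeric(1)), origin = "1970-01-01")
    ord <- order(enc_ts, enc_ids)
    enc_ids <- enc_ids[ord]
    enc_ts <- enc_ts[ord]
    if (length(enc_ids) < 2) {
      n_excluded <- n_excluded + 1L
      next
    }
    elapsed_first <- as.numeric(enc_ts - enc_ts[1])
    elapsed_prev <- c(0, diff(as.numeric(enc_ts)))
    encounters <- vector("list", length(enc_ids))
    for (i in seq_along(enc_ids)) {
      sub <- ev[ev$encounter_id == enc_ids[i], , drop = FALSE]
      lab <- sub[sub$view == "lab", , drop = FALSE]
      lab_codes <- if (abnormal_only) {
        unique(lab$code[lab$abnormal_flag])
      } else {
        unique(lab$code)
      }
      encounters[[i]] <- list(
        encounter_id = enc_ids[i],
        timestamp = enc_ts[i],
        codes = list(
          diagnosis  = sort(unique(sub$code[sub$view == "diagnosis"])),
          medication = sort(unique(sub$code[sub$view == "medication"])),
          lab        = sort(lab_codes)
        ),
        elapsed_first = elapsed_first[i],
        elapsed_prev = elapsed_prev[i]
      )
    }
    timelines[[pid]] <- structure(
      list(patient_id = pid, mortality = as.integer(mort),
           encounters = encounters),
      class = "patient_timeline")
  }
  structure(timelines, class = "ehr_cohort", n_excluded = n_excluded,
            abnormal_only = abnormal_only)
}

#' Export a cohort back to an event data frame
#'
#' The inverse of [build_cohort()] up to the cohort rules already applied
#' (retained lab codes are emitted with `abnormal_flag = TRUE` when the cohort
#' was built in abnormal-only mode).
#'
#' @param cohort an `ehr_cohort`.
#' @return a data frame of clinical events.
#' @export
cohort_events <- function(cohort) {
  rows <- lapply(cohort, function(tl) {
    do.call(rbind, lapply(tl$encounters, function(enc) {
      view <- rep(.views, lengths(enc$codes[.views]))
      code <- unlist(enc$codes[.views], use.names = FALSE)
      if (length(code) == 0) return(NULL)
      data.frame(patient_id = unname(tl$patient_id),
                 encounter_id = unname(enc$encounter_id),
                 timestamp = enc$timestamp, view = view, code = unname(code),
                 abnormal_flag = ifelse(view == "lab", TRUE, NA),
                 mortality = tl$mortality, stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  out
}

#' Build per-view code vocabularies from a training cohort
#'
#' One vocabulary per view, indices assigned lexicographically by code
#' (1-based, contiguous). Vocabularies must be built from the training split
#' only; codes first seen at validation/test time are treated as
#' out-of-vocabulary downstream.
#'
#' @param cohort an `ehr_cohort` restricted to training-split patients.
#' @return a named list of `code_vocabulary` objects
#'   (`diagnosis`, `medication`, `lab`).
#' @export
build_vocabularies <- function(cohort) {
  if (length(cohort) == 0) stop("cannot build vocabularies from an empty cohort")
  vocabs <- lapply(.views, function(v) {
    codes <- sort(unique(unlist(lapply(cohort, function(tl) {
      unlist(lapply(tl$encounters, function(enc) enc$codes[[v]]),
             use.names = FALSE)
    }), use.names = FALSE)))
    structure(list(view = v, codes = codes, size = length(codes)),
              class = "code_vocabulary")
  })
  vocabs <- stats::setNames(vocabs, .views)
  attr(vocabs, "fit_ids") <- sort(names(cohort))
  vocabs
}

#' Map codes to vocabulary indices (and back)
#'
#' @param vocab a `code_vocabulary`.
#' @param codes character vector of codes.
#' @return integer indices (`NA` for out-of-vocabulary codes).
#' @export
vocab_index <- function(vocab, codes) match(codes, vocab$codes)

#' @rdname vocab_index
#' @param indices integer vocabulary indices.
#' @export
vocab_code <- function(vocab, indices) vocab$codes[indices]

#' Encode one encounter as three multi-hot indicator vectors
#'
#' @param encounter one element of a `patient_timeline`'s `encounters`.
#' @param vocabs vocabularies from [build_vocabularies()].
#' @return a `multi_hot_views` object: a named list of 0/1 vectors (one per
#'   view) with attribute `n_oov`, the number of documented codes absent from
#'   the vocabularies (skipped, never an error).
#' @export
encode_encounter <- function(encounter, vocabs) {
  n_oov <- 0L
  views <- lapply(.views, function(v) {
    x <- numeric(vocabs[[v]]$size)
    idx <- vocab_index(vocabs[[v]], encounter$codes[[v]])
    n_oov <<- n_oov + sum(is.na(idx))
    x[idx[!is.na(idx)]] <- 1
    x
  })
  structure(stats::setNames(views, .views), class = "multi_hot_views",
            n_oov = n_oov)
}

#' Remove the final encounter before prediction
#'
#' Predictions are made from all but the last encounter (whose information
#' would not be available at prediction time); the mortality label is
#' unchanged. This is why the cohort requires at least two encounters.
#'
#' @param timeline a `patient_timeline` with at least two encounters.
#' @return the timeline with its final encounter removed.
#' @export
prepare_model_input <- function(timeline) {
  n <- length(timeline$encounters)
  if (n < 2) {
    stop("prepare_model_input requires >= 2 encounters (cohort rule violated)")
  }
  timeline$encounters <- timeline$encounters[-n]
  timeline
}

# apply prepare_model_input across a cohort
prepare_cohort <- function(cohort) {
  out <- lapply(cohort, prepare_model_input)
  attributes(out) <- attributes(cohort)
  out
}

#' Partition patient ids into train/validation/test splits
#'
#' Ids are shuffled with the given seed, then assigned
#' `floor(r_train * N)` to train, `floor(r_val * N)` to validation, and the
#' remainder to test — the integer convention that reproduces the
#' (5275, 753, 1509) partition of 7537 patients at ratios (0.7, 0.1, 0.2).
#'
#' @param patient_ids character vector of unique patient ids.
#' @param ratios numeric length-3 vector (train, validation, test) summing to 1.
#' @param seed integer seed; fixed seed gives identical membership.
#' @return a `cohort_splits` object with elements `train`, `validation`,
#'   `test`, `seed`, `ratios`.
#' @export
split_cohort <- function(patient_ids, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  patient_ids <- as.character(patient_ids)
  stopifnot(!anyDuplicated(patient_ids))
  n <- length(patient_ids)
  if (n < 3) stop("need at least 3 patients to form three splits")
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive numbers")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  shuffled <- withr::with_seed(seed, sample(patient_ids))
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  structure(list(
    train = shuffled[seq_len(n_train)],
    validation = shuffled[n_train + seq_len(n_val)],
    test = shuffled[(n_train + n_val + 1):n],
    seed = as.integer(seed),
    ratios = ratios
  ), class = "cohort_splits")
}

#' Merge the train and validation splits
#'
#' After hyperparameters are selected on the validation split, the final model
#' is retrained on the combined train+validation set.
#'
#' @param splits a `cohort_splits`.
#' @return character vector of patient ids, disjoint from `splits$test`.
#' @export
merge_train_validation <- function(splits) {
  c(splits$train, splits$validation)
}

#' Write / read a split manifest
#'
#' @param splits a `cohort_splits`.
#' @param path JSON file path.
#' @export
write_split_manifest <- function(splits, path) {
  jsonlite::write_json(
    list(seed = splits$seed, ratios = splits$ratios,
         train = splits$train, validation = splits$validation,
         test = splits$test),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = m$train, validation = m$validation, test = m$test,
                 seed = as.integer(m$seed), ratios = m$ratios),
            class = "cohort_splits")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  n_enc <- sum(vapply(x, function(tl) length(tl$encounters), integer(1)))
  prev <- if (length(x)) mean(vapply(x, `[[`, integer(1), "mortality")) else NA
  cat(sprintf("<ehr_cohort> %d patients, %d encounters, mortality %.1f%%, %d excluded (<2 encounters)\n",
              length(x), n_enc, 100 * prev, attr(x, "n_excluded")))
  invisible(x)
}

# subset a cohort by patient ids, preserving class/attributes
cohort_subset <- function(cohort, ids) {
  out <- unclass(cohort)[intersect(ids, names(cohort))]
  structure(out, class = "ehr_cohort", n_excluded = 0L,
            abnormal_only = attr(cohort, "abnormal_only"))
}
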