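# Zero-out ablation attribution and risk-factor ranking.
#
# The attribution weight of a feature for a patient is the reduction in the
# model's predicted death probability when the feature's indicator is zeroed
# in every encounter of the patient. Weights can be negative (protective
# features). Population-level weights average the patient-level weights over
# the patients who document the feature.

#' Reference to a feature (view + code)
#'
#' @param view one of `"diagnosis"`, `"medication"`, `"lab"`.
#' @param code code string; must exist in the view's vocabulary.
#' @param vocabs vocabularies.
#' @return a `feature_ref` list with `view`, `code`, `index`.
#' @export
feature_ref <- function(view, code, vocabs) {
  stopifnot(view %in% .views)
  idx <- vocab_index(vocabs[[view]], code)
  if (is.na(idx)) stop("unknown feature: ", view, " code ", code)
  structure(list(view = view, code = code, index = idx), class = "feature_ref")
}

# zero the feature out of (selected encounters of) a timeline
ablate_timeline <- function(timeline, view, code, encounters = NULL) {
  which_enc <- if (is.null(encounters)) seq_along(timeline$encounters) else
    encounters
  for (i in which_enc) {
    timeline$encounters[[i]]$codes[[view]] <-
      setdiff(timeline$encounters[[i]]$codes[[view]], code)
  }
  timeline
}

feature_present <- function(timeline, view, code, encounters = NULL) {
  which_enc <- if (is.null(encounters)) seq_along(timeline$encounters) else
    encounters
  any(vapply(timeline$encounters[which_enc],
             function(enc) code %in% enc$codes[[view]], logical(1)))
}

#' Attribution weight of one feature by zero-out ablation
#'
#' `weight = p(original) - p(ablated)` where the ablated timeline has the
#' feature's indicator set to 0 in every encounter (or in the selected
#' encounters). A feature absent from all (selected) encounters returns
#' exactly 0 without recomputation.
#'
#' @param model a `clout_model` or `logistic_baseline`.
#' @param timeline a prepared `patient_timeline`.
#' @param feature a [feature_ref()] (or list with `view` and `code`; the code
#'   must exist in the model's vocabulary).
#' @param encounters optional integer vector restricting the ablation to
#'   specific encounters; default ablates across the whole timeline.
#' @return the attribution weight (probability reduction; may be negative).
#' @export
ablate_feature <- function(model, timeline, feature, encounters = NULL) {
  if (!inherits(feature, "feature_ref")) {
    feature <- feature_ref(feature$view, feature$code, model$vocabs)
  } else if (is.na(vocab_index(model$vocabs[[feature$view]], feature$code))) {
    stop("unknown feature: ", feature$view, " code ", feature$code)
  }
  if (!feature_present(timeline, feature$view, feature$code, encounters)) {
    return(0)
  }
  p_full <- predict_mortality(model, timeline)
  p_abl <- predict_mortality(
    model, ablate_timeline(timeline, feature$view, feature$code, encounters))
  p_full - p_abl
}

# all distinct in-vocabulary features documented anywhere in a timeline
documented_features <- function(timeline, vocabs) {
  out <- do.call(rbind, lapply(.views, function(v) {
    codes <- unique(unlist(lapply(timeline$encounters,
                                  function(enc) enc$codes[[v]]),
                           use.names = FALSE))
    codes <- codes[!is.na(vocab_index(vocabs[[v]], codes))]
    if (length(codes) == 0) return(NULL)
    data.frame(view = v, code = codes, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(view = character(), code = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

rank_records <- function(df) {
  df <- df[order(-df$weight, df$view, df$code), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Patient-level risk factor ranking
#'
#' One attribution record per distinct feature documented anywhere in the
#' timeline, ranked by descending weight (ties broken by view then code). For
#' sequence models all ablated variants of the patient are scored in one
#' batched forward pass; the result is identical to looping [ablate_feature()]
#' over the documented features.
#'
#' @param model a `clout_model` or `logistic_baseline`.
#' @param timeline a prepared `patient_timeline`.
#' @return a data frame (`view`, `code`, `weight`, `rank`) of class
#'   `ranked_risk_factors` with attribute `scope = "patient"`.
#' @export
patient_risk_factors <- function(model, timeline) {
  feats <- documented_features(timeline, model$vocabs)
  if (nrow(feats) == 0) {
    out <- data.frame(view = character(), code = character(),
                      weight = numeric(), rank = integer())
    return(structure(out, class = c("ranked_risk_factors", "data.frame"),
                     scope = "patient"))
  }
  variants <- c(list(original = timeline),
                lapply(seq_len(nrow(feats)), function(i) {
                  ablate_timeline(timeline, feats$view[i], feats$code[i])
                }))
  p <- unname(predict_cohort(model, variants))
  feats$weight <- p[1] - p[-1]
  out <- rank_records(feats)
  structure(out, class = c("ranked_risk_factors", "data.frame"),
            scope = "patient")
}

#' Population-level risk factor ranking
#'
#' For every feature, the population attribution weight is the mean of its
#' patient-level weights over the patients who document it (its `support`);
#' features documented by no patient are omitted.
#'
#' @param model a `clout_model` or `logistic_baseline`.
#' @param cohort a list of prepared `patient_timeline`s (typically the test
#'   split, to interpret the deployed model).
#' @return list with `pooled` (all views ranked together) and `per_view`
#'   (a named list of per-view rankings); each a `ranked_risk_factors` data
#'   frame with columns `view`, `code`, `weight`, `support`, `rank`.
#' @export
population_risk_factors <- function(model, cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  per_patient <- lapply(cohort, function(tl) {
    patient_risk_factors(model, tl)[, c("view", "code", "weight")]
  })
  all_w <- do.call(rbind, per_patient)
  agg <- stats::aggregate(weight ~ view + code, data = all_w,
                          FUN = function(w) c(mean(w), length(w)))
  pooled <- data.frame(view = agg$view, code = agg$code,
                       weight = agg$weight[, 1],
                       support = as.integer(agg$weight[, 2]),
                       stringsAsFactors = FALSE)
  pooled <- rank_records(pooled)
  pooled <- structure(pooled, class = c("ranked_risk_factors", "data.frame"),
                      scope = "population")
  per_view <- lapply(.views, function(v) {
    df <- pooled[pooled$view == v, c("view", "code", "weight", "support")]
    structure(rank_records(df),
              class = c("ranked_risk_factors", "data.frame"),
              scope = "population")
  })
  list(pooled = pooled, per_view = stats::setNames(per_view, .views))
}

#' A stratified sampling plan over ranked risk factors
#'
#' Default bins follow the review design: ranks 1–20, 21–50, and the
#' remainder, with a fixed number of uniform draws per bin.
#'
#' @param draws integer draws per bin.
#' @param bins list of `(lower, upper)` rank boundaries; `Inf` for open end.
#' @return a `sampling_plan`.
#' @export
sampling_plan <- function(draws = c(4L, 4L, 4L),
                          bins = list(c(1, 20), c(21, 50), c(51, Inf))) {
  stopifnot(length(draws) == length(bins))
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  stopifnot(all(lo <= hi), all(head(hi, -1) < tail(lo, -1)))  # disjoint, ordered
  structure(list(draws = as.integer(draws), bins = bins),
            class = "sampling_plan")
}

# draw per-bin uniform samples without replacement from one ranking,
# excluding features in `exclude` (a "view code" key vector)
sample_from_ranking <- function(ranking, plan, exclude = character(),
                                scope, list_name) {
  key <- paste(ranking$view, ranking$code)
  picks <- list()
  for (b in seq_along(plan$bins)) {
    lo <- plan$bins[[b]][1]; hi <- plan$bins[[b]][2]
    in_bin <- which(ranking$rank >= lo & ranking$rank <= hi &
                      !(key %in% exclude))
    if (length(in_bin) < plan$draws[b]) {
      stop("bin ", b, " of the ", scope, " ranking (", list_name,
           ") holds ", length(in_bin), " eligible features but ",
           plan$draws[b], " draws were requested")
    }
    sel <- in_bin[sample.int(length(in_bin), plan$draws[b])]
    picks[[b]] <- data.frame(scope = scope, list = list_name, bin = b,
                             view = ranking$view[sel], code = ranking$code[sel],
                             rank = ranking$rank[sel], stringsAsFactors = FALSE)
    exclude <- c(exclude, key[sel])
  }
  do.call(rbind, picks)
}

#' Stratified sampling of risk factors for blinded expert review
#'
#' Draws features per bin from the patient-level ranking, then from each
#' per-view population ranking, excluding features already selected (so the
#' review set is maximised); the combined selection is returned in a seeded
#' random order suitable for blind review, with provenance (scope, source
#' list, bin, rank) in the `provenance` attribute.
#'
#' @param patient_ranking a patient-level `ranked_risk_factors`.
#' @param population_rankings named list of per-view population rankings (as
#'   in [population_risk_factors()]`$per_view`).
#' @param patient_plan a [sampling_plan()] for the patient list (default
#'   4 + 4 + 4 = 12 features).
#' @param population_plan a [sampling_plan()] applied to each per-view
#'   population list (default 2 + 2 + 2 per view, 18 features in total).
#' @param seed integer seed; selection and blinding order are deterministic.
#' @return data frame (`view`, `code`, `presentation_order`) of the shuffled
#'   review set, with attribute `provenance`.
#' @export
stratified_sample_features <- function(patient_ranking, population_rankings,
                                       patient_plan = sampling_plan(),
                                       population_plan =
                                         sampling_plan(draws = c(2L, 2L, 2L)),
                                       seed = 1L) {
  stopifnot(nrow(patient_ranking) > 0)
  withr::with_seed(derive_seed(seed, "stratified_sample"), {
    picks <- sample_from_ranking(patient_ranking, patient_plan,
                                 scope = "patient", list_name = "patient")
    exclude <- paste(picks$view, picks$code)
    for (v in names(population_rankings)) {
      more <- sample_from_ranking(population_rankings[[v]], population_plan,
                                  exclude = exclude, scope = "population",
                                  list_name = v)
      picks <- rbind(picks, more)
      exclude <- c(exclude, paste(more$view, more$code))
    }
    ord <- sample.int(nrow(picks))
  })
  out <- data.frame(view = picks$view[ord], code = picks$code[ord],
                    presentation_order = seq_len(nrow(picks)),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- picks
  attr(out, "seed") <- as.integer(seed)
  out
}
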