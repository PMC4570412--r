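# Test registry, 0/1/2 scoring, total-score aggregation and agreement
# reporting. The registry mirrors the supported-test inventory: 5 Shoulder,
# 4 Elbow, 2 Forearm, 7 Hand, 3 Wrist and 2 Coordination/Speed movements
# (23 in total), each with required sensors, preprocessing constants and a
# feature recipe.

FMA_CATEGORIES <- c("Shoulder", "Elbow", "Forearm", "Hand", "Wrist",
                    "Coordination/Speed")

.registry_cache <- new.env(parent = emptyenv())

#' The built-in FMA test registry
#'
#' Loads the shipped YAML registry (or a user-supplied override) into a
#' stable, ordered list of test definitions. Each definition carries
#' `test_id`, `label`, `category`, `required_sensors`, `recipe` and
#' `preprocess` (a [preprocess_params()]).
#'
#' @param path YAML registry file; default is the registry shipped with the
#'   package.
#' @return named list of `test_definition` objects, class `fma_registry`.
#' @export
fma_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.registry_cache$default)) return(.registry_cache$default)
    path <- system.file("extdata", "registry.yaml", package = "fmassess",
                        mustWork = TRUE)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$tests) || !length(doc$tests))
    stop("fma_registry: registry file has no tests")
  dflt <- doc$defaults$preprocess
  defs <- lapply(doc$tests, function(t) {
    pp <- t$preprocess
    if (is.null(pp)) pp <- dflt
    for (nm in names(dflt)) if (is.null(pp[[nm]])) pp[[nm]] <- dflt[[nm]]
    pp <- preprocess_params(pp$target_frames, pp$movement_threshold,
                            pp$filter_window, pp$end_quiet_time,
                            pp$gyro_rest_threshold)
    if (!(t$category %in% FMA_CATEGORIES))
      stop("fma_registry: unknown category: ", t$category)
    bad <- setdiff(unlist(t$required_sensors), SENSOR_NAMES)
    if (length(bad))
      stop("fma_registry: unknown sensor(s): ", paste(bad, collapse = ", "))
    def <- structure(list(test_id = t$test_id, label = t$label,
                          category = t$category,
                          required_sensors = unlist(t$required_sensors),
                          recipe = t$recipe, preprocess = pp),
                     class = "test_definition")
    if (recipe_dimension(def$recipe) <= 0)
      stop("fma_registry: test ", t$test_id, " has an empty recipe")
    def
  })
  names(defs) <- vapply(defs, `[[`, character(1), "test_id")
  if (anyDuplicated(names(defs)))
    stop("fma_registry: duplicated test ids")
  reg <- structure(defs, class = "fma_registry")
  if (default) .registry_cache$default <- reg
  reg
}

registry_lookup <- function(registry, test_id, error = TRUE) {
  def <- registry[[test_id]]
  if (is.null(def) && error)
    stop("unknown test id: ", test_id)
  def
}

#' @export
print.fma_registry <- function(x, ...) {
  cat(sprintf("<fma_registry> %d supported tests\n", length(x)))
  for (cat_ in FMA_CATEGORIES) {
    ids <- names(x)[vapply(x, function(d) d$category == cat_, logical(1))]
    if (length(ids))
      cat(sprintf("  %-18s %s\n", cat_, paste(ids, collapse = ", ")))
  }
  invisible(x)
}

#' Score one recorded test movement
#'
#' Pure composition of [extract_features()] and
#' [predict()][predict.fma_model].
#'
#' @param bundle a [recording_bundle()].
#' @param model a fitted `fma_model` for the same test.
#' @param registry the test registry.
#' @return integer score 0, 1 or 2.
#' @export
score_movement <- function(bundle, model, registry = fma_registry()) {
  if (!inherits(model, "fma_model")) stop("score_movement: not an fma_model")
  if (!identical(model$test_id, bundle$test_id))
    stop(sprintf("score_movement: model is for test '%s', bundle is '%s'",
                 model$test_id, bundle$test_id))
  fv <- extract_features(bundle, registry = registry)
  predict(model, fv)
}

#' Total FMA-style score
#'
#' @param scores vector (or named mapping) of per-test scores, each 0/1/2.
#' @return integer arithmetic sum.
#' @export
total_score <- function(scores) {
  scores <- unlist(scores)
  if (!length(scores)) return(0L)
  if (!all(scores %in% 0:2))
    stop("total_score: scores must all be 0, 1 or 2")
  as.integer(sum(scores))
}

#' Agreement between automated and clinician totals
#'
#' `(1 - |auto - clinician| / clinician) * 100`, reported to two decimals.
#' 100 exactly when the totals agree.
#'
#' @param auto_total automated total score.
#' @param clinician_total clinician total score (`> 0`).
#' @return agreement percentage, rounded to 2 decimals.
#' @export
#' @examples
#' score_agreement(29, 30)   # 96.67
#' score_agreement(30, 33)   # 90.91
score_agreement <- function(auto_total, clinician_total) {
  if (!is.numeric(clinician_total) || clinician_total <= 0)
    stop("score_agreement: clinician total must be > 0")
  round((1 - abs(auto_total - clinician_total) / clinician_total) * 100, 2)
}

#' Assess one subject from a set of recordings
#'
#' Scores every recording with its per-test model and aggregates into an
#' FMA-style report. Recordings whose test is outside the registry are
#' reported as clinician-administered, never scored 0; recordings that fail
#' validation or lack a model are skipped with a reason.
#'
#' @param bundles list of [recording_bundle()]s for one subject.
#' @param models named list of fitted `fma_model`s, keyed by test id.
#' @param registry the test registry.
#' @return an `assessment_report`: `subject_id`, named `scores`, integer
#'   `total` and a named character vector `skipped`.
#' @export
assess <- function(bundles, models, registry = fma_registry()) {
  stopifnot(length(bundles) > 0)
  subject <- unique(vapply(bundles, `[[`, character(1), "subject_id"))
  if (length(subject) != 1)
    stop("assess: bundles span multiple subjects")
  scores <- integer(0)
  skipped <- character(0)
  for (b in bundles) {
    id <- b$test_id
    if (is.null(registry_lookup(registry, id, error = FALSE))) {
      skipped[id] <- "clinician-administered (unsupported test)"
      next
    }
    if (is.null(models[[id]])) {
      skipped[id] <- "no trained model"
      next
    }
    s <- tryCatch(score_movement(b, models[[id]], registry),
                  error = function(e) e)
    if (inherits(s, "error")) {
      skipped[id] <- conditionMessage(s)
    } else {
      scores[id] <- s
    }
  }
  structure(list(subject_id = subject, scores = scores,
                 total = total_score(scores), skipped = skipped),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> subject=%s\n", x$subject_id))
  for (id in names(x$scores))
    cat(sprintf("  %-28s %d\n", id, x$scores[[id]]))
  cat(sprintf("  total: %d / %d\n", x$total, 2L * length(x$scores)))
  if (length(x$skipped)) {
    cat("  skipped:\n")
    for (id in names(x$skipped))
      cat(sprintf("    %-26s %s\n", id, x$skipped[[id]]))
  }
  invisible(x)
}
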