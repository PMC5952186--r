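#' Published worked-example fixture tables
#'
#' Transcription of the source study's two printed result tables, used as
#' worked examples for the positivity and key-target filters. `table2` holds
#' the positive module-enrichment rows (module, seed gene group, overlap
#' count, Fisher p-value, fold proportion) for modules M146, M203, M194,
#' M195, M204 and M95, whose printed per-module positive-result counts are
#' 12, 8, 4, 2, 2 and 1. `table4` holds the shortest-path summaries of the
#' two reported key targets, CRH and NPPA, against their key module and the
#' aggregate co-morbid `Diseases` and `Symptoms` groups.
#'
#' @return list with data frames `table2` (`module_label`, `group_name`,
#'   `group_category`, `k`, `p_value`, `proportion`) and `table4` (`source`,
#'   `group_name`, `group_category`, `min_sp`, `max_sp`, `avg_sp`).
#' @examples
#' fx <- paper_fixture()
#' table(fx$table2$module_label)
#' @export
paper_fixture <- function() {
  t2 <- function(module, group, category, k, p, prop) {
    data.frame(module_label = module, group_name = group,
               group_category = category, k = k, p_value = p,
               proportion = prop, stringsAsFactors = FALSE)
  }
  table2 <- rbind(
    t2("M146", "Anxiety (D)", "disease", 13L, 2.90e-06, 4.770082),
    t2("M146", "Chest pain (S)", "symptom", 25L, 0.0221, 1.38308),
    t2("M146", "Dizziness (S)", "symptom", 28L, 0.012776, 1.429755),
    t2("M146", "Insomnia (S)", "symptom", 8L, 0.00495, 2.877702),
    t2("M146", "Palpitations (S)", "symptom", 12L, 1.27e-09, 10.55632),
    t2("M146", "Shortness of breath (S)", "symptom", 5L, 0.033574, 2.538544),
    t2("M146", "Thirst (S)", "symptom", 23L, 5.05e-16, 9.163804),
    t2("M146", "Pinellia Tuber(Ban Xia)", "herb", 25L, 1.40e-05, 2.487102983),
    t2("M146", "Poria coco(Fu Ling)", "herb", 8L, 0.041464852, 1.821802935),
    t2("M146", "Diseases", "aggregate-diseases", 14L, 0.000434, 3.083373),
    t2("M146", "Herbs", "aggregate-herbs", 34L, 0.002613, 1.809648),
    t2("M146", "Symptoms", "aggregate-symptoms", 57L, 9.68e-06, 2.129997),
    t2("M203", "Arrhythmia (D)", "disease", 3L, 0.005047, 8.311160088),
    t2("M203", "Autonomic dysfunction (D)", "disease", 1L, 0.015491, 63.71889401),
    t2("M203", "Chest pain (S)", "symptom", 8L, 0.013648, 2.270036),
    t2("M203", "Dizziness (S)", "symptom", 9L, 0.00725, 2.357119),
    t2("M203", "Palpitations (S)", "symptom", 2L, 0.019188, 9.023954),
    t2("M203", "Thirst (S)", "symptom", 3L, 0.011237, 6.130623),
    t2("M203", "Diseases", "aggregate-diseases", 5L, 0.002451, 6.064949),
    t2("M203", "Symptoms", "aggregate-symptoms", 13L, 0.006585, 2.732289),
    t2("M194", "Chest pain (S)", "symptom", 9L, 0.000671, 3.298646),
    t2("M194", "Dizziness (S)", "symptom", 9L, 0.001176, 3.044612),
    t2("M194", "Insomnia (S)", "symptom", 3L, 0.007411, 7.149291),
    t2("M194", "Symptoms", "aggregate-symptoms", 12L, 0.001491, 3.783921),
    t2("M195", "Chest pain (S)", "symptom", 4L, 0.049971, 2.513254),
    t2("M195", "Symptoms", "aggregate-symptoms", 7L, 0.014961, 3.779208),
    t2("M204", "Cardiac sympathetic remodeling (D)", "disease", 1L, 0.049286,
       19.47464789),
    t2("M204", "Dizziness (S)", "symptom", 24L, 0.025127, 1.37222),
    t2("M95", "Chest pain (S)", "symptom", 3L, 0.020438, 4.398194)
  )

  t4 <- function(source, group, category, mn, mx, avg) {
    data.frame(source = source, group_name = group, group_category = category,
               min_sp = mn, max_sp = mx, avg_sp = avg,
               stringsAsFactors = FALSE)
  }
  table4 <- rbind(
    t4("CRH", "Diseases", "aggregate-diseases", 0L, 7L, 2.943452),
    t4("CRH", "Symptoms", "aggregate-symptoms", 0L, 9L, 2.998833),
    t4("CRH", "M146", "module", 0L, 4L, 1.686667),
    t4("NPPA", "Diseases", "aggregate-diseases", 0L, 6L, 2.705357),
    t4("NPPA", "Symptoms", "aggregate-symptoms", 0L, 9L, 2.740698),
    t4("NPPA", "M203", "module", 0L, 3L, 1.548387)
  )
  list(table2 = table2, table4 = table4)
}

#' Apply the pipeline filters to the fixture tables
#'
#' `fixture_positivity()` applies the `p < alpha` positivity rule to the
#' transcribed enrichment rows, giving the per-module positive-result counts.
#' `fixture_key_calls()` turns the transcribed path summaries into a
#' key-target call table (`is_key` iff `avg_sp < threshold`, strict) that
#' [intersect_key_targets()] accepts; the printed tables omit reachability
#' counts, so `n_reachable`/`n_total` are `NA` (finite printed averages imply
#' reachability).
#'
#' @param fixture list from [paper_fixture()].
#' @param alpha positivity threshold (default 0.05).
#' @param threshold key-target cutoff on `avg_sp` (default 3, strict).
#' @return `fixture_positivity()`: data frame (`module_label`,
#'   `n_positive`), modules in decreasing count order; `fixture_key_calls()`:
#'   a `key_target_calls`-shaped data frame.
#' @export
fixture_positivity <- function(fixture = paper_fixture(), alpha = 0.05) {
  rows <- fixture$table2
  pos <- tapply(rows$p_value < alpha, rows$module_label, sum)
  out <- data.frame(module_label = names(pos), n_positive = as.integer(pos),
                    stringsAsFactors = FALSE)
  num <- as.integer(sub("^M", "", out$module_label))
  out <- out[order(-out$n_positive, num), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname fixture_positivity
#' @export
fixture_key_calls <- function(fixture = paper_fixture(), threshold = 3) {
  rows <- fixture$table4
  rows$n_reachable <- NA_integer_
  rows$n_total <- NA_integer_
  rows$is_key <- is.finite(rows$avg_sp) & rows$avg_sp < threshold
  rows$threshold <- threshold
  class(rows) <- c("key_target_calls", "data.frame")
  rows
}
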