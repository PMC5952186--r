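make_counts <- function(labels, n) {
  data.frame(module_label = labels, n_positive = as.integer(n),
             stringsAsFactors = FALSE)
}

test_that("top_n and min_positive selection rules behave as documented", {
  counts <- make_counts(c("M146", "M203", "M194"), c(12, 8, 4))
  sel <- select_key_modules(counts, "top_n", 2)
  expect_equal(sel$selected, c("M146", "M203"))
  sel2 <- select_key_modules(counts, "min_positive", 5)
  expect_equal(sel2$selected, c("M146", "M203"))
  expect_warning(empty <- select_key_modules(make_counts("M1", 1),
                                             "min_positive", 2),
                 "no module qualifies")
  expect_length(empty$selected, 0)
})

test_that("selection equals an independent sort-and-slice on random counts", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    counts <- make_counts(paste0("M", sample(1:200, k)),
                          sample(0:15, k, replace = TRUE))
    param <- sample(1:5, 1)
    sel <- select_key_modules(counts, "top_n", param)
    # oracle: order by count desc, module number asc, slice, drop zeros
    ord <- counts[order(-counts$n_positive,
                        as.integer(sub("M", "", counts$module_label))), ]
    ord <- ord[ord$n_positive > 0, ]
    expect_equal(sel$selected, head(ord$module_label, param))
    selm <- select_key_modules(counts, "min_positive", param)
    expect_setequal(selm$selected,
                    counts$module_label[counts$n_positive >= param])
  }
})

fake_calls <- function(df) {
  df$threshold <- 3
  class(df) <- c("key_target_calls", "data.frame")
  df
}

call_row <- function(src, group, cat, avg) {
  data.frame(source = src, group_name = group, group_category = cat,
             min_sp = 0L, max_sp = 5L, avg_sp = avg, n_reachable = 10L,
             n_total = 10L, is_key = !is.na(avg) & avg < 3,
             stringsAsFactors = FALSE)
}

test_that("candidate calling is the strict three-way conjunction", {
  sel <- select_key_modules(make_counts(c("Ma", "Mb"), c(5, 3)), "top_n", 2)
  calls <- fake_calls(rbind(
    call_row("CRH", "Ma", "module", 1.7),
    call_row("CRH", "Diseases", "aggregate-diseases", 2.943452),
    call_row("CRH", "Symptoms", "aggregate-symptoms", 2.998833),
    call_row("LOSER", "Ma", "module", 1.2),
    call_row("LOSER", "Diseases", "aggregate-diseases", 2.1),
    call_row("LOSER", "Symptoms", "aggregate-symptoms", 3.4)
  ))
  cand <- intersect_key_targets(calls, sel)
  expect_equal(cand$gene, "CRH")
  expect_equal(cand$modules_hit, "Ma")
  expect_equal(cand$mean_avg_sp, mean(c(1.7, 2.943452, 2.998833)))
  # conjunction soundness: stored averages all under the threshold
  expect_true(all(c(cand$avg_sp_diseases, cand$avg_sp_symptoms) < 3))
})

test_that("candidates match an exhaustive conjunction check on random calls", {
  set.seed(612)
  sel <- select_key_modules(make_counts(c("M1", "M2"), c(4, 2)), "top_n", 2)
  targets <- paste0("T", 1:6)
  for (rep in 1:10) {
    rows <- list()
    for (tg in targets) {
      rows[[length(rows) + 1]] <- call_row(tg, "M1", "module", runif(1, 1, 5))
      rows[[length(rows) + 1]] <- call_row(tg, "M2", "module", runif(1, 1, 5))
      rows[[length(rows) + 1]] <-
        call_row(tg, "Diseases", "aggregate-diseases", runif(1, 1, 5))
      rows[[length(rows) + 1]] <-
        call_row(tg, "Symptoms", "aggregate-symptoms", runif(1, 1, 5))
    }
    calls <- fake_calls(do.call(rbind, rows))
    cand <- intersect_key_targets(calls, sel)
    expected <- Filter(function(tg) {
      cc <- calls[calls$source == tg, ]
      any(cc$is_key[cc$group_name %in% c("M1", "M2")]) &&
        cc$is_key[cc$group_name == "Diseases"] &&
        cc$is_key[cc$group_name == "Symptoms"]
    }, targets)
    expect_setequal(cand$gene, expected)
    expect_true(!is.unsorted(cand$mean_avg_sp))
  }
})

test_that("missing aggregate groups are an input error", {
  sel <- select_key_modules(make_counts("M1", 3), "top_n", 1)
  calls <- fake_calls(rbind(
    call_row("T1", "M1", "module", 1.5),
    call_row("T1", "Diseases", "aggregate-diseases", 2)
  ))
  expect_error(intersect_key_targets(calls, sel), "aggregate-symptoms")
})

test_that("pathway overlaps are plain set intersections", {
  module <- paste0("G", 1:20)
  keys <- paste0("G", 1:5)
  ann <- structure(list(
    sets = list(all = module, none = paste0("H", 1:10),
                half = paste0("G", 11:25)),
    description = c(all = "", none = "", half = "")
  ), class = "annotation_collection")
  ov <- pathway_key_overlap(ann, module, keys)
  expect_equal(ov$n_pathway_gene, c(20L, 0L, 10L))
  expect_equal(ov$n_key_protein, c(5L, 0L, 0L))
  expect_true(all(ov$n_key_protein <= ov$n_pathway_gene))

  set.seed(31)
  pool <- paste0("G", 1:60)
  for (i in 1:10) {
    sets <- lapply(1:5, function(j) sample(pool, sample(5:30, 1)))
    names(sets) <- paste0("s", 1:5)
    ann2 <- structure(list(sets = sets,
                           description = stats::setNames(rep("", 5), names(sets))),
                      class = "annotation_collection")
    mod <- sample(pool, 25)
    key <- sample(mod, 6)
    ov2 <- pathway_key_overlap(ann2, mod, key)
    for (j in 1:5) {
      expect_equal(ov2$n_pathway_gene[j], length(intersect(sets[[j]], mod)))
      expect_equal(ov2$n_key_protein[j],
                   length(intersect(intersect(sets[[j]], mod), key)))
    }
  }
})

test_that("run_pipeline writes the full report bundle with sane schemas", {
  spec <- synthetic_spec(seed = 3)
  dir <- withr::local_tempdir()
  b <- generate_input_bundle(spec, file.path(dir, "in"))
  res <- run_pipeline(list(network = b$network, seed_sets = b$seed_sets,
                           herb_table = b$herb_table, gmt = b$gmt,
                           seed = 3),
                      out_dir = file.path(dir, "out"))
  expect_true(all(file.exists(res$files)))
  enr <- read_enrichment_report(res$files[["enrichment"]])
  expect_true(all(c("module_label", "group_name", "k", "p_value",
                    "proportion", "positive") %in% names(enr)))
  paths_tab <- read_path_report(res$files[["path_summaries"]])
  expect_true(all(c("source", "group_name", "min_sp", "max_sp", "avg_sp",
                    "n_reachable", "n_total", "is_key") %in% names(paths_tab)))
  ov <- read.delim(res$files[["pathway_overlap"]])
  expect_true(all(ov$n_key_protein <= ov$n_pathway_gene))
  # conjunction soundness against the recorded calls
  for (g in res$candidates$gene) {
    cc <- res$calls[res$calls$source == g &
                      (res$calls$group_name %in% res$selection$selected |
                         res$calls$group_category %in%
                           c("aggregate-diseases", "aggregate-symptoms")), ]
    agg <- cc[cc$group_category %in% c("aggregate-diseases",
                                       "aggregate-symptoms"), ]
    expect_true(all(agg$avg_sp < 3))
  }
})
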