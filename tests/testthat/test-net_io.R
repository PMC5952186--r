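test_that("gene normalization uppercases, trims, and is idempotent", {
  expect_equal(normalize_gene(c(" crh", "Nppa ")), c("CRH", "NPPA"))
  x <- c("a", " b\t", "GeNe1")
  expect_identical(normalize_gene(normalize_gene(x)), normalize_gene(x))
  expect_error(normalize_gene(""), "empty")
  expect_error(normalize_gene("TWO WORDS"), "whitespace")
})

test_that("edge lists load with normalization, dedup and self-loop dropping", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tC"))
  net <- read_network(f)
  expect_equal(network_nodes(net), c("A", "B", "C"))
  expect_equal(nrow(network_edges(net)), 2L)

  f2 <- withr::local_tempfile(lines = c("A\tB", "b\ta", "A\tA"))
  net2 <- read_network(f2)
  expect_equal(network_nodes(net2), c("A", "B"))
  expect_equal(nrow(network_edges(net2)), 1L)
  rep2 <- load_report(net2)
  expect_equal(rep2$n_duplicates, 1L)
  expect_equal(rep2$n_self_loops, 1L)
})

test_that("malformed lines are fatal by default and skippable on request", {
  f <- withr::local_tempfile(lines = c("A\tB", "ONLYONE", "B\tC"))
  expect_error(read_network(f), "line 2")
  net <- read_network(f, skip_bad_lines = TRUE)
  expect_equal(load_report(net)$n_malformed, 1L)
  expect_equal(network_nodes(net), c("A", "B", "C"))
})

test_that("SIF format reads node-relation-node lines, relation ignored", {
  f <- withr::local_tempfile(lines = c("A\tpp\tB", "B\tpp\tC\tD", "# comment"))
  net <- read_network(f, format = "sif")
  expect_equal(network_nodes(net), c("A", "B", "C", "D"))
  expect_equal(nrow(network_edges(net)), 3L)
  f2 <- withr::local_tempfile(lines = c("A\tpp"))
  expect_error(read_network(f2, format = "sif"), "line 1")
})

test_that("node/edge counts of a random edge file match a set-based tally", {
  set.seed(42)
  lhs <- sample(LETTERS, 100, replace = TRUE)
  rhs <- sample(letters, 100, replace = TRUE)
  f <- withr::local_tempfile(lines = paste(lhs, rhs, sep = "\t"))
  net <- read_network(f)

  # independent line-by-line set accumulation
  nodes <- character()
  edges <- character()
  loops <- 0L
  for (i in seq_len(100)) {
    a <- toupper(lhs[i]); b <- toupper(rhs[i])
    nodes <- union(nodes, c(a, b))
    if (a == b) loops <- loops + 1L
    else edges <- union(edges, paste(min(a, b), max(a, b)))
  }
  expect_equal(sort(network_nodes(net)), sort(nodes))
  expect_equal(nrow(network_edges(net)), length(edges))
  expect_equal(load_report(net)$n_self_loops, loops)
})

test_that("load report conserves line counts", {
  f <- withr::local_tempfile(
    lines = c("# header", "A\tB", "A\tB", "C\tC", "BAD", "D\tE", ""))
  net <- read_network(f, skip_bad_lines = TRUE)
  r <- load_report(net)
  expect_equal(r$n_kept + r$n_self_loops + r$n_duplicates, r$n_pairs)
  expect_equal(r$n_pairs + r$n_malformed + r$n_comment, 7L)
})

test_that("network TSV round-trips node and edge sets exactly", {
  set.seed(7)
  pairs <- random_edge_pairs(30, 0.1, seed = 7)
  net <- network_from_pairs(pairs, 30) # includes isolated nodes
  f <- withr::local_tempfile()
  write_network(net, f)
  back <- read_network(f)
  expect_identical(network_nodes(back), network_nodes(net))
  expect_identical(network_edges(back), network_edges(net))
})

test_that("seed sets are filtered to the network, aggregated, and logged", {
  net <- ppi_network(c("A", "B"), c("B", "C"))
  f <- withr::local_tempfile(lines = c(
    "name\tcategory\tgene",
    "set1\tdisease\tA", "set1\tdisease\tB",
    "set2\tdisease\tB", "set2\tdisease\tC",
    "ghost\tsymptom\tX"
  ))
  expect_message(seeds <- read_seed_sets(f, net), "ghost")
  expect_setequal(names(seeds$sets), c("set1", "set2", "Diseases"))
  expect_equal(seeds$sets$Diseases$genes, c("A", "B", "C"))
  expect_equal(seeds$sets$Diseases$category, "aggregate-diseases")
  lg <- seeds$log
  expect_false(lg$kept[lg$name == "ghost"])
  # filtering never adds genes
  for (s in seeds$sets) expect_true(all(s$genes %in% network_nodes(net)))
})

test_that("seed set reader rejects unknown categories and all-empty inputs", {
  net <- ppi_network("A", "B")
  f <- withr::local_tempfile(lines = c("name\tcategory\tgene", "s\tpathway\tA"))
  expect_error(read_seed_sets(f, net), "unknown seed set category")
  f2 <- withr::local_tempfile(lines = c("name\tcategory\tgene", "s\tdisease\tZ"))
  expect_error(suppressMessages(read_seed_sets(f2, net)), "empty")
})

test_that("retained seed gene counts match an independent membership scan", {
  set.seed(11)
  pairs <- random_edge_pairs(40, 0.1, seed = 11)
  net <- network_from_pairs(pairs, 40)
  pool <- c(network_nodes(net), paste0("X", 1:40)) # 50% in-network
  rows <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(name = paste0("s", i), category = "disease",
               gene = sample(pool, 12), stringsAsFactors = FALSE)
  }))
  f <- withr::local_tempfile()
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  seeds <- suppressMessages(read_seed_sets(f, net))
  for (i in 1:5) {
    nm <- paste0("s", i)
    expected <- sum(unique(rows$gene[rows$name == nm]) %in% network_nodes(net))
    got <- if (nm %in% names(seeds$sets)) length(seeds$sets[[nm]]$genes) else 0L
    expect_equal(got, expected)
  }
})

test_that("herb table collapses duplicate triples and groups per-herb sets", {
  f <- withr::local_tempfile(lines = c(
    "herb\tingredient\ttarget\tsource",
    "BanXia\tGABA\tCRH\thit",
    "BanXia\tGABA\tCRH\ttcmid",
    "BanXia\tL-Arg\tNPPA\thit"
  ))
  rec <- read_herb_table(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_duplicates"), 1L)
  sets <- herb_seed_sets(rec)
  expect_equal(sets$sets$BanXia$genes, c("CRH", "NPPA"))
  expect_equal(sets$sets$Herbs$category, "aggregate-herbs")
})

test_that("herb record count equals an independent unique-triple tally", {
  set.seed(3)
  base <- data.frame(
    herb = sample(paste0("H", 1:5), 400, replace = TRUE),
    ingredient = sample(paste0("I", 1:30), 400, replace = TRUE),
    target = sample(paste0("T", 1:50), 400, replace = TRUE),
    source = "db", stringsAsFactors = FALSE
  )
  tab <- rbind(base, base[sample(400, 100), ]) # planted duplicates
  tab <- tab[sample(nrow(tab)), ]
  f <- withr::local_tempfile()
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_herb_table(f)
  expected <- nrow(unique(tab[, c("herb", "ingredient", "target")]))
  expect_equal(nrow(rec), expected)
})

test_that("herb table reader requires its mandatory columns", {
  f <- withr::local_tempfile(lines = c("herb\tingredient", "a\tb"))
  expect_error(read_herb_table(f), "missing required column")
})

test_that("GMT collections parse, validate, and round-trip", {
  f <- withr::local_tempfile(lines = c(
    "setA\tdesc A\tg1\tg2\tg3",
    "setB\tdesc B\tg2\tg4"
  ))
  ann <- read_gmt(f)
  expect_equal(names(ann$sets), c("setA", "setB"))
  expect_equal(ann$sets$setA, c("G1", "G2", "G3"))
  f2 <- withr::local_tempfile()
  write_gmt(ann, f2)
  expect_equal(read_gmt(f2)$sets, ann$sets)
  fbad <- withr::local_tempfile(lines = c("setA\tonly-two-cols"))
  expect_error(read_gmt(fbad), "fewer than 3")
  fdup <- withr::local_tempfile(lines = c("s\td\tg1", "s\td\tg2"))
  expect_error(read_gmt(fdup), "duplicate")
})
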