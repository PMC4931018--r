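test_that("the five event templates are detected from definitions", {
  # IR: intron of one isoform inside an exon of the other
  t1 <- mk_tx("t1", "c1", "+", c(0L, 200L), c(100L, 300L))
  t2 <- mk_tx("t2", "c1", "+", 0L, 300L)
  ev <- pairwise_events(t1, t2)
  expect_equal(ev$mode, "IR")
  expect_equal(ev$detail, "retained:100-200")

  # A3 vs A5 resolved by strand: same junction pair flips mode
  a <- mk_tx("a", "c1", "+", c(0L, 200L, 400L), c(100L, 300L, 500L))
  b <- mk_tx("b", "c1", "+", c(0L, 230L, 400L), c(100L, 300L, 500L))
  expect_equal(pairwise_events(a, b)$mode, "A3")
  am <- a %>% mutate(strand = "-"); bm <- b %>% mutate(strand = "-")
  expect_equal(pairwise_events(am, bm)$mode, "A5")

  # ES: internal exon absent, outer flanking sites shared
  full <- mk_tx("f", "c1", "+", c(0L, 200L, 400L), c(100L, 300L, 500L))
  skip <- mk_tx("s", "c1", "+", c(0L, 400L), c(100L, 500L))
  ev <- pairwise_events(full, skip)
  expect_equal(ev$mode, "ES")
  expect_equal(ev$detail, "skipped:200-300")

  # MXE: two disjoint internal exons, each in exactly one isoform
  x1 <- mk_tx("x1", "c1", "+", c(0L, 200L, 600L), c(100L, 300L, 700L))
  x2 <- mk_tx("x2", "c1", "+", c(0L, 400L, 600L), c(100L, 500L, 700L))
  expect_equal(pairwise_events(x1, x2)$mode, "MXE")

  expect_error(pairwise_events(t1, mk_tx("z", "c2", "+", 0L, 100L)),
               "same chromosome")
})

test_that("pairwise events are symmetric, identity-empty, and mirror-dual", {
  sim <- std_fixture()
  ase <- sim$reads$truth$as_events
  reads <- sim$reads$reads
  get1 <- function(id) reads[reads$transcript_id == id, ]
  for (i in seq_len(nrow(ase))) {
    t1 <- get1(ase$isoform_1[i]); t2 <- get1(ase$isoform_2[i])
    e12 <- pairwise_events(t1, t2); e21 <- pairwise_events(t2, t1)
    expect_equal(e12$mode, e21$mode)
    expect_equal(e12$detail, e21$detail)
    expect_equal(nrow(pairwise_events(t1, t1)), 0L)
  }
  # strand duality on random perturbed pairs: a strand flip alone swaps
  # A5<->A3; mirroring coordinates and flipping strand together is the
  # identity on transcript geometry and preserves every mode
  set.seed(99)
  L <- 100000L
  swap <- c(IR = "IR", ES = "ES", MXE = "MXE", OTHER = "OTHER", A3 = "A5", A5 = "A3")
  for (i in 1:50) {
    t1 <- random_tx("r1", len = L, n_ex = sample(3:5, 1), strand = "+")
    t2 <- perturb_tx(t1)
    ev <- pairwise_events(t1, t2)
    evf <- pairwise_events(t1 %>% mutate(strand = "-"),
                           t2 %>% mutate(strand = "-"))
    expect_equal(sort(unname(swap[ev$mode])), sort(evf$mode))
    evm <- pairwise_events(mirror_tx(t1, L), mirror_tx(t2, L))
    expect_equal(sort(ev$mode), sort(evm$mode))
  }
})

test_that("planted event modes are recovered exactly", {
  sim <- std_fixture()
  ase <- sim$reads$truth$as_events
  reads <- sim$reads$reads
  for (i in seq_len(nrow(ase))) {
    t1 <- reads[reads$transcript_id == ase$isoform_1[i], ]
    t2 <- reads[reads$transcript_id == ase$isoform_2[i], ]
    ev <- pairwise_events(t1, t2)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$mode, ase$mode[i])
  }
})

test_that("gene_events deduplicates shared events and tabulates modes", {
  # three isoforms; the IR difference appears in two pairs but counts once
  t1 <- mk_tx("t1", "c1", "+", c(0L, 200L), c(100L, 300L), gene_id = "g1")
  t2 <- mk_tx("t2", "c1", "+", 0L, 300L, gene_id = "g1")
  t3 <- mk_tx("t3", "c1", "+", c(10L, 200L), c(100L, 310L), gene_id = "g1")
  res <- gene_events(bind_rows(t1, t2, t3))
  expect_equal(sum(res$events$mode == "IR"), 1L)
  expect_equal(sum(res$mode_freq$n), 1L)
  # mono-isoform gene yields nothing
  expect_equal(nrow(gene_events(t1)$events), 0L)
  # fixture: planted mode distribution recovered by gene-level enumeration
  sim <- std_fixture()
  ase <- sim$reads$truth$as_events
  as_reads <- sim$reads$reads %>%
    filter(.data$transcript_id %in% c(ase$isoform_1, ase$isoform_2))
  res <- gene_events(as_reads)
  found <- res$events %>% count(.data$mode)
  planted <- ase %>%
    distinct(.data$gene_id, .data$mode, .keep_all = TRUE) # same-gene same-mode dedup
  expect_gte(sum(found$n), nrow(planted %>% distinct(.data$gene_id, .data$mode)))
  expect_setequal(found$mode, unique(ase$mode))
})

test_that("tissue-exclusive sets and the overlap matrix match a recount", {
  tx <- bind_rows(
    mk_tx("i1", "c1", "+", 0L, 100L, tissues = list("pollen")),
    mk_tx("i2", "c1", "+", 200L, 300L, tissues = list(c("pollen", "root"))),
    mk_tx("i3", "c1", "+", 400L, 500L, tissues = list("root"))
  )
  res <- tissue_specific_sets(tx)
  excl <- res$exclusive
  expect_equal(excl$n_exclusive[excl$tissue == "pollen"], 1L)
  expect_equal(excl$transcript_ids[excl$tissue == "pollen"][[1]], "i1")
  expect_equal(res$overlap["pollen", "root"], 1L)
  expect_equal(res$overlap["pollen", "pollen"], 2L)
  expect_error(tissue_specific_sets(mk_tx("x", "c1", "+", 0L, 10L)),
               "empty tissue")

  sim <- std_fixture()
  sres <- tissue_specific_sets(sim$reads$reads)
  sizes <- purrr::map_int(sim$reads$reads$tissues, length)
  for (t in sres$exclusive$tissue) {
    oracle <- sum(sizes == 1 &
                    purrr::map_lgl(sim$reads$reads$tissues, ~ identical(.x, t)))
    expect_equal(sres$exclusive$n_exclusive[sres$exclusive$tissue == t], oracle)
  }
})
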