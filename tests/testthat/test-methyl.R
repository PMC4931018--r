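test_that("site_level implements C/(C+T) with undefined zero-depth sites", {
  expect_equal(site_level(3L, 1L), 0.75)
  expect_equal(site_level(0L, 5L), 0)
  expect_true(is.na(site_level(0L, 0L)))
  expect_error(site_level(-1L, 2L), "negative")
})

test_that("junction stacking reproduces hand-computed cells on both strands", {
  # one '+' junction with intron (100, 200); a few cytosines at known offsets
  j <- tibble(chrom = "c1", strand = "+", intron_start = 100L, intron_end = 200L)
  meth <- tibble(
    chrom = "c1",
    pos = c(99L, 100L, 199L, 200L, 99L),
    strand = c("+", "+", "+", "+", "-"),
    context = c("CG", "CHH", "CHG", "CG", "CG"),
    count_c = c(3L, 1L, 4L, 0L, 2L),
    count_t = c(1L, 3L, 0L, 2L, 2L))
  prof <- as_tibble(stack_junctions(j, meth))
  cell <- function(sc, posn, ctx, strd) {
    prof$level[prof$site_class == sc & prof$position == posn &
                 prof$context == ctx & prof$strand_rel == strd]
  }
  expect_equal(cell("donor", -1L, "CG", "sense"), 0.75)       # pos 99, + strand
  expect_equal(cell("donor", -1L, "CG", "antisense"), 0.5)    # pos 99, - strand
  expect_equal(cell("donor", -1L, "CG", "combined"), 5 / 8)
  expect_equal(cell("donor", 1L, "CHH", "sense"), 0.25)       # pos 100
  expect_equal(cell("acceptor", -1L, "CHG", "sense"), 1)      # pos 199
  expect_equal(cell("acceptor", 1L, "CG", "sense"), 0)        # pos 200
  # the same genomic fixture seen from a '-' junction mirrors sides
  jm <- j %>% mutate(strand = "-")
  pm <- as_tibble(stack_junctions(jm, meth))
  cellm <- function(sc, posn, ctx, strd) {
    pm$level[pm$site_class == sc & pm$position == posn &
               pm$context == ctx & pm$strand_rel == strd]
  }
  # genomic pos 99 is now acceptor-exonic (+1): the '+' cytosine there is
  # antisense to the transcript, the '-' cytosine is sense
  expect_equal(cellm("acceptor", 1L, "CG", "antisense"), 0.75)
  expect_equal(cellm("acceptor", 1L, "CG", "sense"), 0.5)
  expect_equal(cellm("donor", -1L, "CG", "antisense"), 0)     # pos 200, '+' strand
})

test_that("combined counts decompose exactly into sense + antisense", {
  cfg <- sim_config(seed = 8, n_genes = 20,
                    category_counts = c(a = 0, b = 0, c = 0, d = 0, e = 0,
                                        f = 0, g = 0, h = 0))
  ann <- simulate_annotation(cfg, simulate_genome(cfg))
  meth <- simulate_methylation(cfg, ann$genome, ann$annotation)
  prof <- as_tibble(stack_junctions(tx_junctions(ann$annotation), meth))
  wide <- prof %>%
    select("site_class", "position", "context", "strand_rel", "sum_c", "sum_ct") %>%
    tidyr::pivot_wider(names_from = "strand_rel",
                       values_from = c("sum_c", "sum_ct"))
  expect_equal(wide$sum_c_combined, wide$sum_c_sense + wide$sum_c_antisense)
  expect_equal(wide$sum_ct_combined, wide$sum_ct_sense + wide$sum_ct_antisense)
  # pooled level lies between min and max contributing site levels (in [0,1])
  expect_true(all(prof$level >= 0 & prof$level <= 1, na.rm = TRUE))
})

test_that("uniform methylation yields flat junction and metagene profiles", {
  cfg <- sim_config(seed = 9, n_genes = 20,
                    methylation_donor = c(CG = 0.2, CHG = 0.2, CHH = 0.2),
                    methylation_acceptor = c(CG = 0.2, CHG = 0.2, CHH = 0.2),
                    category_counts = c(a = 0, b = 0, c = 0, d = 0, e = 0,
                                        f = 0, g = 0, h = 0))
  ann <- simulate_annotation(cfg, simulate_genome(cfg))
  meth <- simulate_methylation(cfg, ann$genome, ann$annotation)
  prof <- as_tibble(stack_junctions(tx_junctions(ann$annotation), meth))
  lv <- prof$level[prof$strand_rel == "combined" & !is.na(prof$level) &
                     prof$sum_ct >= 200]
  expect_lt(max(abs(lv - 0.2)), 0.15)
  expect_lt(abs(mean(lv) - 0.2), 0.01)
  mg <- metagene_profile(ann$annotation, meth)
  expect_equal(nrow(mg), 3 * 100 * 3)  # 300 bins x 3 contexts
  expect_lt(abs(mean(mg$level, na.rm = TRUE) - 0.2), 0.01)
  expect_lt(max(abs(mg$level - 0.2), na.rm = TRUE), 0.1)
})

test_that("depth 0 produces an empty methylation table", {
  cfg <- sim_config(seed = 9, read_depth = 0)
  expect_equal(nrow(simulate_methylation(cfg, Biostrings::DNAStringSet(c(c1 = "ACGT")),
                                         mk_tx("t", "c1", "+", 0L, 4L))), 0L)
})

test_that("stratification routes junctions by gene and drops the 11-19 gap", {
  gene_counts <- tibble(gene_id = c("g1", "g2", "g3", "g4"),
                        n_isoforms = c(1L, 5L, 15L, 22L))
  junctions <- tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "c1", strand = "+",
    intron_start = c(100L, 300L, 500L, 700L),
    intron_end = c(200L, 400L, 600L, 800L))
  meth <- tibble(chrom = "c1", pos = c(100L, 300L, 500L, 700L), strand = "+",
                 context = "CG", count_c = 2L, count_t = 2L)
  expect_message(res <- stratify_by_isoform_count(gene_counts, junctions, meth),
                 "11-19")
  expect_equal(res$excluded_genes, "g3")
  expect_setequal(unique(res$profiles$stratum), c("1", "2-10", ">=20"))
  one <- res$profiles %>%
    filter(.data$stratum == "1", .data$strand_rel == "sense", .data$sum_ct > 0)
  expect_true(all(one$level == 0.5))
})

test_that("minus-strand metagene bins mirror the mirrored fixture", {
  tx_p <- mk_tx("p", "c1", "+", 2000L, 3000L)
  L <- 5000L
  tx_m <- mirror_tx(tx_p, L)
  set.seed(2)
  pos <- sample(0:(L - 1), 1500)
  meth_p <- tibble(chrom = "c1", pos = as.integer(sort(pos)), strand = "+",
                   context = "CG",
                   count_c = rbinom(1500, 10, 0.3), count_t = 0L)
  meth_p$count_t <- 10L - meth_p$count_c
  meth_m <- meth_p %>%
    mutate(pos = as.integer(L - 1L - .data$pos), strand = "-") %>%
    arrange(.data$pos)
  a <- metagene_profile(tx_p, meth_p)
  b <- metagene_profile(tx_m, meth_m)
  expect_equal(a$level, b$level)
  expect_equal(a$sum_ct, b$sum_ct)
})
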