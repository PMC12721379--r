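test_that("clr transform matches the hand-evaluated formula", {
  m <- matrix(c(0, 3, 15), 1, dimnames = list("s1", c("a", "b", "c")))
  got <- clr_transform(m, pseudocount = 1)
  # counts + 1 = (1, 4, 16); geometric mean 4; ln(c(1,4,16)/4)
  expect_equal(as.vector(got), log(c(1, 4, 16) / 4), tolerance = 1e-12)
  expect_equal(as.vector(got), c(-1.3863, 0, 1.3863), tolerance = 1e-4)

  uniform <- matrix(1, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_true(all(clr_transform(uniform) == 0))
})

test_that("clr rows center at zero and match a brute-force oracle", {
  set.seed(42)
  counts <- matrix(rpois(20 * 8, 50), 20, 8,
                   dimnames = list(paste0("s", 1:20), paste0("sp", 1:8)))
  got <- clr_transform(counts, pseudocount = 1)
  expect_lt(max(abs(rowSums(got))), 1e-8)
  oracle <- t(apply(counts + 1, 1, function(v) log(v / exp(mean(log(v))))))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("clr with zero pseudocount is scale invariant on positive counts", {
  set.seed(7)
  counts <- matrix(rpois(5 * 6, 40) + 1, 5, 6,
                   dimnames = list(paste0("s", 1:5), paste0("sp", 1:6)))
  a <- clr_transform(counts, pseudocount = 0)
  b <- clr_transform(counts * 37.5, pseudocount = 0)
  expect_equal(unname(a), unname(b), tolerance = 1e-10, ignore_attr = TRUE)
  zeroed <- counts
  zeroed[1, 1] <- 0
  expect_error(clr_transform(zeroed, pseudocount = 0), "positive")
  expect_error(clr_transform(-counts), "nonnegative")
})

test_that("abundance table rejects duplicates and bad relative abundances", {
  m <- matrix(1, 2, 2, dimnames = list(c("s1", "s1"), c("a", "b")))
  expect_error(abundance_table(m), "duplicate sample")
  m2 <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("a", "a")))
  expect_error(abundance_table(m2), "duplicate species")
  m3 <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(abundance_table(m3, rel_abundance = m3 * 60), "exceed 100")
  # unclassified fraction below 100% is fine
  expect_s3_class(abundance_table(m3, rel_abundance = m3 * 40),
                  "abundance_table")
})

test_that("profile reader merges disjoint species with zero fill", {
  d <- withr::local_tempdir()
  write_profile <- function(path, clades, rel, reads) {
    df <- data.frame(clade_name = clades, relative_abundance = rel,
                     estimated_number_of_reads_from_the_clade = reads)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_profile(file.path(d, "A.tsv"),
                c("k__Bacteria", "k__Bacteria|s__X"), c(100, 60), c(900, 500))
  write_profile(file.path(d, "B.tsv"),
                c("k__Bacteria|s__Y", "k__Bacteria|s__Y|t__SGB1"),
                c(40, 40), c(300, 300))
  tab <- read_abundance_profiles(file.path(d, c("A.tsv", "B.tsv")))
  expect_setequal(tab$species_ids, c("X", "Y"))
  expect_equal(tab$read_counts["A", "X"], 500)
  expect_equal(tab$read_counts["A", "Y"], 0)   # zero-filled union
  expect_equal(tab$read_counts["B", "Y"], 300) # strain row ignored
  expect_equal(tab$rel_abundance["B", "Y"], 40)
})

test_that("profile reader flags rank-free files, bad headers, duplicates", {
  d <- withr::local_tempdir()
  genus_only <- file.path(d, "G.tsv")
  write.table(data.frame(clade_name = "k__Bacteria|g__Bact",
                         relative_abundance = 10,
                         estimated_number_of_reads_from_the_clade = 5),
              genus_only, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_abundance_profiles(genus_only), "no species-level")
  bad <- file.path(d, "bad.tsv")
  writeLines(c("foo\tbar", "1\t2"), bad)
  expect_error(read_abundance_profiles(bad), "malformed profile header")
  expect_error(read_abundance_profiles(c(genus_only, genus_only)),
               "duplicate sample")
})

test_that("profile round trip reproduces the generated matrix", {
  d <- withr::local_tempdir()
  cfg <- tiny_config(n_samples = 12)
  sim <- simulate_abundances(cfg)
  paths <- write_abundance_profiles(sim$abundance, d)
  back <- read_abundance_profiles(unname(paths),
                                  sample_ids = names(paths))
  expect_equal(back$read_counts[sim$abundance$sample_ids,
                                sim$abundance$species_ids],
               sim$abundance$read_counts)
  expect_equal(back$rel_abundance[sim$abundance$sample_ids,
                                  sim$abundance$species_ids],
               sim$abundance$rel_abundance, tolerance = 1e-10)
})

test_that("stratified reader maps totals, strata and unclassified", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ec.tsv")
  writeLines(c(
    "# Gene Family\tS1\tS2",
    "UNMAPPED\t10\t10",
    "3.2.1.18\t10\t0",
    "3.2.1.18|g__G.s__SpeciesA\t4\t0",
    "3.2.1.18|unclassified\t2\t0",
    "3.2.1.23\t5\t5",
    "3.2.1.23|g__G.s__SpeciesB\t5\t4"), f)
  tab <- read_stratified_ec_table(f)
  expect_equal(unname(community_totals(tab)["S1", "3.2.1.18"]), 10)
  s <- tab$strata
  expect_equal(s$cpm[s$ec == "3.2.1.18" & s$species == "SpeciesA"], 4)
  expect_equal(s$cpm[s$ec == "3.2.1.18" & s$species == "UNCLASSIFIED"], 2)
  expect_false("UNMAPPED" %in% tab$ec_ids)
})

test_that("stratified reader imputes missing totals and rejects excess", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ec.tsv")
  writeLines(c("# Gene Family\tS1",
               "3.2.1.18|g__G.s__SpeciesA\t4",
               "3.2.1.23\t5",
               "3.2.1.23|g__G.s__SpeciesB\t5"), f)
  expect_warning(tab <- read_stratified_ec_table(f), "imputed")
  expect_equal(unname(community_totals(tab)["S1", "3.2.1.18"]), 4)

  f2 <- file.path(d, "bad.tsv")
  writeLines(c("# Gene Family\tS1",
               "3.2.1.18\t1",
               "3.2.1.18|g__G.s__SpeciesA\t4"), f2)
  expect_error(read_stratified_ec_table(f2), "exceed")
})

test_that("stratified table round trip preserves numeric payloads", {
  cfg <- tiny_config(n_samples = 10, n_species = 12)
  sim <- simulate_community(cfg)
  d <- withr::local_tempdir()
  f <- file.path(d, "mt.tsv")
  write_stratified_ec_table(sim$transcription, f)
  back <- read_stratified_ec_table(f)
  o1 <- sim$transcription$strata
  o1 <- o1[order(o1$sample, o1$ec, o1$species), ]
  o2 <- back$strata[order(back$strata$sample, back$strata$ec,
                          back$strata$species), ]
  expect_equal(o2$cpm, o1$cpm, tolerance = 1e-9)
  expect_equal(o2[c("sample", "ec", "species")],
               o1[c("sample", "ec", "species")], ignore_attr = TRUE)
})

test_that("default catalog mirrors the shipped enzyme list", {
  cat <- load_ec_catalog()
  expect_equal(nrow(cat), 11)
  sial <- cat[cat$ec_id == "3.2.1.18", ]
  expect_equal(sial$name, "Exo-alpha-sialidase")
  expect_equal(sial$enzyme_class, "glycosyl_hydrolase")
  expect_setequal(cat$ec_id[cat$versatility_excluded],
                  c("3.2.1.22", "3.2.1.23"))
  expect_false(cat$active[cat$ec_id == "3.1.6.14"])
  expect_equal(sum(cat$active), 10)
})

test_that("catalog validation rejects duplicates and malformed ids", {
  df <- data.frame(ec_id = c("3.2.1.18", "3.2.1.18"),
                   name = c("a", "b"),
                   enzyme_class = "glycosyl_hydrolase")
  expect_error(as_ec_catalog(df), "duplicate")
  df2 <- data.frame(ec_id = "3.2.1", name = "a",
                    enzyme_class = "glycosyl_hydrolase")
  expect_error(as_ec_catalog(df2), "malformed EC")
})
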