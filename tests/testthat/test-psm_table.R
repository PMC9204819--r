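test_that("reading a Proteome Discoverer style export preserves rows and missingness", {
  cs <- channel_set()
  hdr <- c("Annotated Sequence", "Master Protein Accessions", "DeltaCn",
           "Isolation Interference [%]", "Average Reporter SN",
           paste0("Abundance: ", cs$labels))
  row1 <- c("PEPTIDEK", "P1", "0.6", "5.5", "40",
            as.character(seq(100, 1000, by = 100)))
  row2 <- c("ANOTHERK", "P2", "0.9", "12", "80",
            as.character(c(200, 300, 400, 500, "", 700, 800, 900, 1000, 1100)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(row1, collapse = "\t"),
               paste(row2, collapse = "\t")), path)

  tab <- read_psm_table(path, cs)
  expect_s3_class(tab, "psm_table")
  expect_equal(nrow(tab$psms), 2L)
  # blank abundance cell becomes missing
  expect_true(is.na(tab$psms[["128C"]][2]))
  expect_equal(sum(is.na(intensity_matrix(tab))), 1L)
  # dialect maps the interference column onto coisolation_pct
  expect_equal(tab$psms$coisolation_pct, c(5.5, 12))
  expect_equal(tab$psms$delta_cn, c(0.6, 0.9))
})

test_that("mandatory columns are enforced and bad numbers are located", {
  cs <- channel_set()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Annotated Sequence\tfoo", "PEPK\t1"), path)
  expect_error(read_psm_table(path, cs), "Abundance: 126")

  hdr <- c("Annotated Sequence", paste0("Abundance: ", cs$labels))
  bad <- c("PEPK", as.character(1:9), "oops")
  writeLines(c(paste(hdr, collapse = "\t"), paste(bad, collapse = "\t")), path)
  expect_error(suppressWarnings(read_psm_table(path, cs)), "row 1")
})

test_that("unmapped quality metrics default to pass-all with a warning", {
  cs <- channel_set()
  hdr <- c("Annotated Sequence", paste0("Abundance: ", cs$labels))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(c("PEPK", as.character(1:10)), collapse = "\t")), path)
  w <- capture_warnings(tab <- read_psm_table(path, cs))
  expect_length(w, 3L)  # delta_cn, coisolation, avg_sn all unmapped
  expect_match(w, "pass-all", all = TRUE)
  expect_equal(tab$psms$delta_cn, 1)
  expect_equal(tab$psms$coisolation_pct, 0)
  expect_equal(tab$psms$avg_sn, Inf)
})

test_that("a write/read round trip reproduces all fields and missing cells", {
  sim <- ref_sim()
  tab <- sim$table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(tab, path)
  back <- read_psm_table(path, tab$channels, canonical_dialect(tab$channels))
  expect_identical(back$psms$psm_id, tab$psms$psm_id)
  expect_identical(back$psms$sequence, tab$psms$sequence)
  expect_identical(back$psms$species, tab$psms$species)
  expect_equal(intensity_matrix(back), intensity_matrix(tab))
  expect_equal(back$psms$avg_sn, tab$psms$avg_sn)
  expect_equal(back$psms$coisolation_pct, tab$psms$coisolation_pct)
})

test_that("species annotation follows the full matched-accession list", {
  m <- matrix(100, 5, 3)
  tab <- toy_table(m, master = c("H1", "H1; Y1", "CRAP1; H2", "XX", ""))
  map <- c(H1 = "human", H2 = "human", Y1 = "yeast")
  ann <- annotate_species(tab, map, contaminants = "CRAP1")
  expect_equal(ann$psms$species,
               c("human", "ambiguous", "contaminant", "unknown", "unknown"))
  expect_error(annotate_species(tab, character()), "species_map")
})

test_that("non-quantifiable exclusion counts reconcile and preserve order", {
  m <- matrix(100, 5, 3)
  tab <- toy_table(m, master = c("H1", "Y1", "H1; Y1", "CRAP1", "H2"))
  ann <- annotate_species(tab, c(H1 = "human", H2 = "human", Y1 = "yeast"),
                          contaminants = "CRAP1")
  res <- exclude_nonquantifiable(ann)
  expect_equal(nrow(res$table$psms), 3L)
  expect_equal(res$counts[["ambiguous"]], 1L)
  expect_equal(res$counts[["contaminant"]], 1L)
  expect_equal(sum(res$counts), 5L - nrow(res$table$psms))
  # survivors keep input order
  expect_equal(res$table$psms$psm_id, c("P001", "P002", "P005"))
  # output is a subset of the input
  expect_true(all(res$table$psms$psm_id %in% tab$psms$psm_id))

  # pure two-species table passes through unchanged
  clean <- annotate_species(toy_table(m, master = rep("H1", 5)),
                            c(H1 = "human"))
  expect_equal(nrow(exclude_nonquantifiable(clean)$table$psms), 5L)

  # all-unknown table empties completely
  unk <- annotate_species(toy_table(m, master = rep("ZZ", 5)),
                          c(H1 = "human"))
  res_unk <- exclude_nonquantifiable(unk)
  expect_equal(nrow(res_unk$table$psms), 0L)
  expect_equal(res_unk$counts[["unknown"]], 5L)
})
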