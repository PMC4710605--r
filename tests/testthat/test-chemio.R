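test_that("parse_structure validates SMILES and counts heavy atoms", {
  m <- parse_structure("CCO")
  expect_s3_class(m, "admet_mol")
  expect_equal(m$heavy_atoms, 3L)

  # methomyl: C5H10N2O2S -> 10 heavy atoms
  expect_equal(parse_structure("CNC(=O)O/N=C(\\C)SC")$heavy_atoms, 10L)

  expect_error(parse_structure("C1CC", id = "rec7"), "rec7",
               class = "admet_parse_error")
  expect_error(parse_structure(""), class = "admet_parse_error")
})

test_that("washing strips salts, keeps the largest fragment and records it", {
  ral <- wash_structure(paste0("Oc1ccc2c(c1)sc(-c1ccc(O)cc1)c2",
                               "C(=O)c1ccc(OCCN2CCCCC2)cc1.Cl"))
  expect_equal(ral$n_fragments_removed, 1L)
  free_base <- canonical_smiles(paste0("Oc1ccc2c(c1)sc(-c1ccc(O)cc1)c2",
                                       "C(=O)c1ccc(OCCN2CCCCC2)cc1"))
  expect_identical(ral$washed_smiles, free_base)

  plain <- wash_structure("CCO")
  expect_equal(plain$n_fragments_removed, 0L)
  expect_identical(plain$washed_smiles, "CCO")

  hg <- wash_structure("[Hg](Cl)Cl")
  expect_equal(hg$n_fragments_removed, 0L)
  expect_false(hg$is_organic)
  expect_true(any(grepl("inorganic", hg$wash_notes)))
})

test_that("neutralization follows the fixed transformation table", {
  # carboxylate salt -> free acid
  acet <- wash_structure("CC(=O)[O-].[Na+]")
  expect_identical(acet$washed_smiles, canonical_smiles("CC(=O)O"))
  # protonated amine -> free base
  amine <- wash_structure("C[NH3+].[Cl-]")
  expect_identical(amine$washed_smiles, canonical_smiles("CN"))
  # nitro group charges are internal, never rewritten
  bron <- wash_structure("OCC(Br)(CO)[N+](=O)[O-]")
  expect_true(grepl("\\[N\\+\\]", bron$washed_smiles))
  expect_true(grepl("\\[O-\\]", bron$washed_smiles))
  # quaternary ammonium keeps its permanent charge after salt stripping
  ddac <- wash_structure("[Cl-].CCCCCCCCCC[N+](C)(C)CCCCCCCCCC")
  expect_true(grepl("\\[N\\+\\]", ddac$washed_smiles))
  expect_equal(ddac$n_fragments_removed, 1L)
})

test_that("washing is idempotent and canonicalization is spelling-invariant", {
  spellings <- list(
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("CCO", "OCC"),
    c("Oc1ccccc1", "c1ccccc1O"),
    c("CNC(=O)ON=C(C)SC", "S(C)C(C)=NOC(=O)NC")
  )
  for (pair in spellings) {
    w1 <- wash_structure(pair[1])
    w2 <- wash_structure(pair[2])
    expect_identical(w1$washed_smiles, w2$washed_smiles)
  }
  fx <- load_table1_fixture()
  smiles <- c(stats::na.omit(fx$actives$smiles), fx$inactives$smiles,
              "CC(=O)[O-].[Na+]", "C[NH3+].[Cl-]")
  for (s in smiles) {
    once <- wash_structure(s)
    twice <- wash_structure(once$washed_smiles)
    expect_identical(twice$washed_smiles, once$washed_smiles)
    expect_equal(twice$n_fragments_removed, 0L)
  }
})

test_that("chemical tables read from CSV with literal-NA annotations intact", {
  fx <- load_table1_fixture()
  expect_equal(nrow(fx$actives), 30L)
  expect_true(all(fx$actives$assay_outcome == "active"))
  # Table footnote "NA" is an annotation value, not a missing cell
  expect_identical(
    fx$actives$absorption_annotation[fx$actives$id == "pharmagsid_47259"], "NA")
  expect_true(is.na(fx$actives$smiles[fx$actives$id == "pharmagsid_47259"]))
  # extra columns preserved
  expect_true(all(c("priority_printed", "registry") %in% names(fx$actives)))
})

test_that("CSV schema and integrity errors are reported by record id", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name\nx,foo", tmp)
  expect_error(read_chemical_table(tmp, "csv"), "smiles",
               class = "admet_schema_error")

  writeLines(c("id,smiles,assay_outcome", "dup1,CCO,active",
               "dup1,CCN,inactive"), tmp)
  expect_error(read_chemical_table(tmp, "csv"), "dup1",
               class = "admet_integrity_error")

  writeLines("id,smiles,assay_outcome", tmp)
  expect_equal(nrow(read_chemical_table(tmp, "csv")), 0L)

  writeLines(c("id,smiles,assay_outcome,ac50_uM", "x,CCO,active,-1"), tmp)
  expect_error(read_chemical_table(tmp, "csv"), class = "admet_integrity_error")
})

test_that("SDF input maps SD tags onto record columns", {
  sdf <- ChemmineR::smiles2sdf(c(eth = "CCO", ace = "CC(=O)O"))
  ChemmineR::datablock(sdf) <- list(
    c(id = "eth", assay_outcome = "inactive", exposure_category = "2"),
    c(id = "ace", assay_outcome = "active", exposure_category = "1"))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, tmp)
  tab <- read_chemical_table(tmp, "sdf")
  expect_equal(tab$id, c("eth", "ace"))
  expect_equal(tab$exposure_category, c(2L, 1L))
  expect_identical(canonical_smiles(tab$smiles[1]), canonical_smiles("CCO"))
})

test_that("reports round-trip through CSV including reason codes and UTF-8", {
  fx <- load_table1_fixture()
  report <- run_workflow(fx$actives)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_report(report, tmp, "csv")
  back <- read_report(tmp)
  expect_equal(nrow(back), 30L)
  expect_equal(back$priority, report$calls$priority)
  expect_equal(ifelse(is.na(back$reasons), "", back$reasons),
               vapply(report$calls$reasons, paste, character(1), collapse = "|"))

  # non-ASCII names survive the round trip
  tab <- data.frame(chemical_id = "x1", name = "β-estradiol",
                    priority = "high", stringsAsFactors = FALSE)
  write_report(tab, tmp, "csv")
  expect_identical(read_report(tmp)$name, "β-estradiol")

  # empty report -> header-only CSV
  write_report(tab[0, ], tmp, "csv")
  expect_equal(nrow(read_report(tmp)), 0L)
})
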