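test_that("parent gate logic matches the brute-force truth table", {
  grid <- generate_triage_grid()
  expect_equal(nrow(grid), 60L)
  for (i in seq_len(nrow(grid))) {
    rec <- grid[i, , drop = FALSE]
    call <- assign_priority_parent(rec)
    ref <- oracle_parent_priority(rec$exposure_category,
                                  rec$absorption_annotation,
                                  rec$distribution_annotation)
    expect_equal(call$priority, ref$priority, info = rec$id)
    expect_equal(call$reasons, ref$reasons, info = rec$id)
    # low priority iff reasons non-empty
    expect_equal(call$priority == "low", length(call$reasons) > 0)
  }
})

test_that("exposure category 4 short-circuits all later gates", {
  call <- assign_priority_parent(make_record("x", exposure = 4L,
                                             absorption = "Yes",
                                             distribution = "Yes"))
  expect_equal(call$priority, "low")
  expect_equal(call$reasons, "no_exposure")
  expect_equal(nrow(call$gate_trace), 1L)
  expect_equal(call$gate_trace$gate, "exposure")
})

test_that("gates are traced in order and annotations beat predictions", {
  call <- assign_priority_parent(
    make_record("x", exposure = 1L, absorption = "Yes", distribution = "Yes"),
    absorption = make_absorption_call("Limited", "mw_gt_500"),
    distribution = make_distribution_call("No", "tpsa_max"))
  expect_equal(call$gate_trace$gate, c("exposure", "absorption", "distribution"))
  expect_equal(call$gate_trace$source, c("annotation", "annotation", "annotation"))
  expect_equal(call$priority, "high")
  expect_false("limited_absorption" %in% call$rank_notes)

  # prediction is consulted only where the annotation is absent
  call2 <- assign_priority_parent(
    make_record("y", exposure = 1L),
    absorption = make_absorption_call("Limited", "mw_gt_500"),
    distribution = make_distribution_call("Yes"))
  expect_equal(call2$gate_trace$source[2:3], c("predicted", "predicted"))
  expect_true("limited_absorption" %in% call2$rank_notes)
  expect_equal(call2$priority, "high")
})

test_that("unknown gate values never demote", {
  call <- assign_priority_parent(make_record("x", exposure = 2L))
  expect_equal(call$priority, "high")
  expect_true(all(grepl("unknown_pass", call$gate_trace$outcome[2:3])))
  # unannotated exposure continues through the tree as well
  call2 <- assign_priority_parent(make_record("y", distribution = "No"))
  expect_equal(call2$priority, "low")
  expect_equal(call2$reasons, "no_bbb_distribution")
})

test_that("metabolism codes and limited absorption become rank notes", {
  call <- assign_priority_parent(make_record("x", exposure = 1L,
                                             absorption = "Limited",
                                             distribution = "Yes",
                                             metabolism = "+"))
  expect_equal(call$priority, "high")
  expect_setequal(call$rank_notes, c("metabolism_activating", "limited_absorption"))
  both <- assign_priority_parent(make_record("y", exposure = 1L,
                                             metabolism = "+-"))
  expect_setequal(both$rank_notes,
                  c("metabolism_activating", "metabolism_detoxifying"))
})

test_that("metabolite routing follows the parent/metabolite decision tree", {
  parent4 <- make_record("par", exposure = 4L, absorption = "NA")
  parent_ok <- make_record("par", exposure = 1L, absorption = "Yes")
  parent_neg <- make_record("par", exposure = 1L, absorption = "Negligible")

  # own environmental exposure: treated as a parent compound
  own <- assign_priority_metabolite(
    make_record("met", exposure = 1L, absorption = "Yes",
                distribution = "Yes", parent = "par"), parent4)
  expect_equal(own$priority, "high")
  expect_equal(own$route, "metabolite_with_own_exposure")

  # no own exposure, parent without exposure -> low
  m1 <- assign_priority_metabolite(
    make_record("met", exposure = 4L, parent = "par"), parent4)
  expect_equal(m1$priority, "low")
  expect_equal(m1$reasons, "no_exposure")

  # no own exposure, parent poorly absorbed -> low
  m2 <- assign_priority_metabolite(
    make_record("met", exposure = 4L, parent = "par"), parent_neg)
  expect_equal(m2$reasons, "negligible_absorption")

  # parent viable: metabolite's own distribution decides
  m3 <- assign_priority_metabolite(
    make_record("met", exposure = 4L, distribution = "No", parent = "par"),
    parent_ok)
  expect_equal(m3$reasons, "no_bbb_distribution")
  m4 <- assign_priority_metabolite(
    make_record("met", exposure = 4L, distribution = "Yes", parent = "par"),
    parent_ok)
  expect_equal(m4$priority, "high")
})

test_that("flagged inactives inherit low priority only from low neighbors", {
  calls <- data.frame(chemical_id = c("ral", "methomyl"),
                      priority = c("low", "high"),
                      stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id = c("zam", "aldicarb", "far"),
    neighbor_id = c("ral", "methomyl", "ral"),
    tanimoto = c(0.76, 0.88, 0.3),
    flagged = c(TRUE, TRUE, FALSE),
    inherited_priority = NA_character_,
    stringsAsFactors = FALSE)
  out <- propagate_neighbor_priority(hits, calls)
  expect_equal(out$inherited_priority, c("low", NA, NA))
  expect_equal(out$possible_false_negative, c(FALSE, TRUE, FALSE))

  bad <- hits; bad$neighbor_id[1] <- "unknown_active"
  expect_error(propagate_neighbor_priority(bad, calls),
               class = "admet_contract_error")
})

test_that("promiscuity flags honor overrides and structural alerts", {
  recs <- data.frame(
    id = c("gv", "bq", "eth", "forced_off"),
    smiles = c("CN(C)c1ccc(cc1)C(c1ccc(N(C)C)cc1)=C1C=CC(C=C1)=[N+](C)C",
               "C(c1ccccc1)[n+]1cccc2ccccc21",
               "CCO",
               "C(c1ccccc1)[n+]1cccc2ccccc21"),
    promiscuity_override = c(TRUE, NA, NA, FALSE),
    stringsAsFactors = FALSE)
  out <- flag_promiscuity(recs)
  expect_equal(out$promiscuity_suspect, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$source, c("override", "alert", "none", "override"))
  expect_match(out$matched_alerts[2], "quaternary_azinium")

  expect_error(
    flag_promiscuity(recs, alerts = data.frame(name = "bad", smarts = "((",
                                               stringsAsFactors = FALSE)),
    class = "admet_config_error")
})

test_that("the full workflow reproduces the case-study triage", {
  fx <- load_table1_fixture()
  report <- run_workflow(fx$actives, fx$inactives)
  s <- report$summary
  expect_equal(s$n_active, 30L)
  expect_equal(s$n_low, 10L)
  expect_equal(s$n_low_by_exposure, 7L)
  expect_equal(s$n_low_by_bbb, 3L)
  expect_equal(s$n_high, 20L)
  expect_equal(s$n_flagged_low_inherited, 1L)
  expect_equal(s$n_possible_false_negatives,
               s$n_flagged_inactives - s$n_flagged_low_inherited)
  # per-chemical agreement with the printed priority column
  printed <- tolower(fx$actives$priority_printed)
  got <- report$calls$priority[match(fx$actives$id, report$calls$chemical_id)]
  expect_equal(got, printed)
  # zamifenacin inherits low priority from raloxifene
  expect_equal(
    report$hits$inherited_priority[report$hits$query_id == "zamifenacin"], "low")
  # both worked-example promiscuity suspects carry the rank note, not a demotion
  suspects <- report$promiscuity$id[report$promiscuity$promiscuity_suspect]
  expect_setequal(suspects, c("gentian_violet", "benzylquinolinium_chloride"))
  expect_equal(s$n_high_non_promiscuous, 18L)
  expect_true(all(report$calls$priority[report$calls$chemical_id %in% suspects]
                  == "high"))
})

test_that("summary counts satisfy the conservation identities", {
  fx <- load_table1_fixture()
  for (report in list(run_workflow(fx$actives, fx$inactives),
                      run_workflow(fx$actives))) {
    s <- report$summary
    expect_equal(s$n_low + s$n_high, s$n_active)
    expect_equal(s$n_low_by_exposure + s$n_low_by_absorption + s$n_low_by_bbb,
                 s$n_low)
    expect_equal(s$n_possible_false_negatives,
                 s$n_flagged_inactives - s$n_flagged_low_inherited)
  }
})

test_that("workflow validation errors are actionable", {
  fx <- load_table1_fixture()
  broken <- fx$actives
  broken$exposure_category[broken$id == "anthralin"] <- NA_integer_
  expect_error(run_workflow(broken), "anthralin",
               class = "admet_annotation_error")

  # a metabolite without independent exposure needs a resolvable parent
  orphan <- fx$actives
  orphan$parent_id[orphan$id == "chlorpyrifos_oxon"] <- "nonexistent"
  orphan$exposure_category[orphan$id == "chlorpyrifos_oxon"] <- NA_integer_
  expect_error(run_workflow(orphan), "chlorpyrifos_oxon",
               class = "admet_linkage_error")
})

test_that("empty active set yields an empty report with zero counts", {
  fx <- load_table1_fixture()
  report <- run_workflow(fx$actives[0, ])
  expect_equal(report$summary$n_active, 0L)
  expect_equal(report$summary$n_low, 0L)
  expect_equal(nrow(report$calls), 0L)
})

test_that("demote_promiscuous turns suspects into low priority", {
  fx <- load_table1_fixture()
  report <- run_workflow(fx$actives,
                         config = triage_config(demote_promiscuous = TRUE))
  suspects <- report$promiscuity$id[report$promiscuity$promiscuity_suspect]
  pri <- report$calls$priority[report$calls$chemical_id %in% suspects]
  expect_true(all(pri == "low"))
  expect_equal(report$summary$n_high, 18L)
})
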