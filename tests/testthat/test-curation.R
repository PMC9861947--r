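rec <- function(value, endpoint = "IC50", units = "nM", fr = "",
                id = "c1", act = "MCF7") {
  data.frame(compound_id = id, activity_id = act, endpoint = endpoint,
             value = value, units = units, failure_reason = fr,
             stringsAsFactors = FALSE)
}

test_that("potency thresholds are strict at 10,000 nM and 50%", {
  expect_equal(label_record(rec(5, units = "uM")), "active")   # 5000 nM
  expect_equal(label_record(rec(9999.9)), "active")
  expect_equal(label_record(rec(10000)), "inactive")           # boundary
  expect_equal(label_record(rec(1e-5, units = "M")), "inactive") # 1e4 nM
  expect_equal(label_record(rec(50, "PCT_INHIBITION", "%")), "inactive")
  expect_equal(label_record(rec(50.1, "PCT_INHIBITION", "%")), "active")
  # Ki and Kact follow the same potency rule (mechanism-of-action tables)
  expect_equal(label_record(rec(2, "Ki", "uM")), "active")
  expect_equal(label_record(rec(20, "Kact", "uM")), "inactive")
})

test_that("NCI60 labeling honors the -log10 GI50 potency cuts", {
  r <- function(v) rec(v, "NEG_LOG_GI50", "")
  expect_equal(label_record(r(9.0), "nci60", "1nM"), "active")   # at cut
  expect_equal(label_record(r(8.99), "nci60", "1nM"), "inactive")
  expect_equal(label_record(r(8.0), "nci60", "10nM"), "active")
  expect_equal(label_record(r(7.0), "nci60", "100nM"), "active")
  expect_equal(label_record(r(6.99), "nci60", "100nM"), "inactive")
  expect_equal(label_record(rec(9, "NEG_LOG_GI50", "", fr = "redefined"),
                            "nci60", "1nM"), "dropped")
  expect_warning(
    lab <- label_record(r(17), "nci60", "1nM"), "sanity window")
  expect_equal(lab, "dropped")
  expect_error(label_record(r(9), "nci60"), "requires nci60_threshold")
})

test_that("unit conversion is exact powers of ten and total on knowns", {
  expect_equal(convert_to_nM(1, "uM"), 1000)
  expect_equal(convert_to_nM(2.5, "M"), 2.5e9)
  expect_equal(convert_to_nM(convert_to_nM(3.7, "uM") / 1000, "uM"),
               convert_to_nM(3.7, "uM"))
  expect_error(convert_to_nM(1, "mg/mL"), "unknown concentration units")
  expect_error(label_record(rec(Inf)), "non-finite")
})

test_that("replicate GI50 aggregation is the median (mean switchable)", {
  expect_equal(aggregate_gi50(c(8.9, 9.1, 9.3)), 9.1)
  expect_equal(aggregate_gi50(7.0), 7.0)
  expect_equal(aggregate_gi50(c(8.0, 9.0)), 8.5)   # even-count average
  expect_equal(aggregate_gi50(c(1, 2, 9), "mean"), 4)
  expect_error(aggregate_gi50(numeric(0)), "no replicate")
})

test_that("activity names normalize and map through synonyms", {
  syn <- c(`mcf7` = "MCF7", `Hl 60` = "HL-60")
  expect_equal(normalize_activity_name("mcf-7", syn), "MCF7")
  expect_equal(normalize_activity_name("MCF 7 ", syn), "MCF7")
  expect_equal(normalize_activity_name("hl-60", syn), "HL-60")
  expect_equal(normalize_activity_name("EKVX"), "EKVX")      # pass-through
  expect_equal(normalize_activity_name(" A549 "), "A549")
})

test_that("conflicts resolve active-wins independent of row order", {
  r2 <- rbind(rec(100), rec(50000))            # active + inactive, same cmp
  extra <- rbind(rec(100, id = "c2"), rec(200, id = "c3"),
                 rec(80000, id = "c4"))
  for (records in list(rbind(r2, extra), rbind(r2[2:1, ], extra))) {
    sets <- suppressMessages(
      build_labeled_sets(records, "chembl_pubchem", min_actives = 1))
    s <- sets$MCF7
    expect_equal(s$label[s$compound_id == "c1"], "active")
  }
})

test_that("labeled sets respect min_actives and record accounting", {
  records <- rbind(rec(100, id = "a1"), rec(200, id = "a2"),
                   rec(300, id = "a3"), rec(90000, id = "i1"),
                   rec(80000, id = "i2"),
                   rec(100, id = "b1", act = "SPARSE"),
                   rec(120, id = "b2", act = "SPARSE"),
                   rec(70000, id = "b3", act = "SPARSE"))
  sets <- suppressMessages(
    build_labeled_sets(records, "chembl_pubchem", min_actives = 3))
  expect_named(sets, "MCF7")                    # SPARSE: only 2 actives
  expect_equal(length(sets$MCF7$compound_id), 5)
  summ <- attr(sets, "summary")
  expect_true(all(summ$n_records_active + summ$n_records_inactive +
                    summ$n_records_dropped ==
                    as.vector(table(records$activity_id)[summ$activity_id])))
  expect_false(summ$retained[summ$activity_id == "SPARSE"])
  # no surviving activity at all is an error
  expect_error(
    suppressMessages(build_labeled_sets(records[6:8, ], "chembl_pubchem",
                                        min_actives = 3)),
    "no activity survived")
})

test_that("NCI60 pipeline drops failures then aggregates replicates", {
  records <- rbind(
    rec(8.9, "NEG_LOG_GI50", "", id = "n1"),
    rec(9.3, "NEG_LOG_GI50", "", id = "n1"),
    rec(9.1, "NEG_LOG_GI50", "", id = "n1", fr = "redefined"),
    rec(6.0, "NEG_LOG_GI50", "", id = "n2"),
    rec(9.5, "NEG_LOG_GI50", "", id = "n3"),
    rec(9.6, "NEG_LOG_GI50", "", id = "n4"))
  sets <- suppressMessages(
    build_labeled_sets(records, "nci60", nci60_threshold = "1nM",
                       min_actives = 1))
  s <- sets$MCF7
  # n1: surviving replicates 8.9, 9.3 -> median 9.1 >= 9 -> active
  expect_equal(s$label[s$compound_id == "n1"], "active")
  expect_equal(s$label[s$compound_id == "n2"], "inactive")
  expect_equal(attr(sets, "summary")$n_dropped, 1)
})

test_that("delimited tables round trip with autodetected separators", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,activity_id,endpoint,value,units",
               "c1,MCF7,IC50,5000,nM"), tf)
  tab <- read_activity_table(tf)
  expect_equal(tab$value, 5000)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("raw\tstd", "mcf-7\tMCF7"), tf2)
  syn <- read_synonym_table(tf2)
  expect_equal(normalize_activity_name("MCF—7", syn), "MCF7")
  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,value", tf3)
  expect_error(read_activity_table(tf3), "missing columns")
})
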