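printed_header <- "@D4LHBFN1:276:C2HKJACXX:4:1101:3448:12374 1:N:0:AGTTCC"

test_that("dialect detection recognizes both header formats and rejects junk", {
  expect_identical(detect_dialect(printed_header), "v1_8_plus")
  expect_identical(detect_dialect("@M1:5:1101:100:200#0/1"), "pre_1_8")
  expect_error(detect_dialect("not-a-header"), "leading '@'")
  expect_error(detect_dialect("@weird stuff here"), "unrecognized")
})

test_that("the documented 1.8+ header parses field by field", {
  id <- parse_identifier(printed_header)
  expect_identical(id$machine_id, "D4LHBFN1")
  expect_identical(id$run_number, 276L)
  expect_identical(id$flowcell_id, "C2HKJACXX")
  expect_identical(id$lane, 4L)
  expect_identical(id$tile, 1101L)
  expect_identical(id$x_coord, 3448L)
  expect_identical(id$y_coord, 12374L)
  expect_identical(id$read_number, 1L)
  expect_identical(id$is_filtered, "N")
  expect_identical(id$control_number, 0L)
  expect_identical(id$index_sequence, "AGTTCC")
})

test_that("pre-1.8 headers parse and omit run/flowcell fields", {
  id <- parse_identifier("@M1:5:1101:100:200#0/1")
  expect_identical(id$machine_id, "M1")
  expect_identical(id$lane, 5L)
  expect_identical(id$tile, 1101L)
  expect_identical(id$x_coord, 100L)
  expect_identical(id$y_coord, 200L)
  expect_identical(id$index_sequence, "0")
  expect_identical(id$read_number, 1L)
  expect_true(is.na(id$run_number))
  expect_true(is.na(id$flowcell_id))
})

test_that("format/parse round-trips on random valid lines of both dialects", {
  set.seed(11)
  for (i in seq_len(1000)) {
    l1 <- random_v18_line()
    expect_identical(format_identifier(parse_identifier(l1)), l1)
    l2 <- random_pre18_line()
    expect_identical(format_identifier(parse_identifier(l2)), l2)
  }
})

test_that("batch inference recovers the five-batch confounded layout", {
  samples <- figure1_samples()
  design <- infer_batches(samples)
  expect_identical(design$n_batches, 5L)
  # planted batch labels are assigned in first-appearance order, matching
  # the layout's own numbering
  expect_identical(design$samples$batch, samples$batch)
})

test_that("batch keys split on any differing component, lane included", {
  one <- data.frame(sample_id = c("a", "b"), species = "human",
                    tissue = c("t1", "t2"),
                    identifier_line = c(
                      "@M:1:FC:4:1101:1:1 1:N:0:AAAAAA",
                      "@M:1:FC:5:1101:1:1 1:N:0:AAAAAA"))
  expect_identical(infer_batches(one)$n_batches, 2L)
  one$identifier_line[2] <- "@M:1:FC:4:2000:99:99 2:Y:0:CCCCCC"
  expect_identical(infer_batches(one)$n_batches, 1L)
})

test_that("batch membership is input-order invariant, labels deterministic", {
  samples <- figure1_samples()
  set.seed(3)
  shuffled <- samples[sample.int(nrow(samples)), ]
  d1 <- infer_batches(samples)
  d2 <- infer_batches(shuffled)
  key1 <- setNames(d1$samples$batch_key, d1$samples$sample_id)
  key2 <- setNames(d2$samples$batch_key, d2$samples$sample_id)
  expect_identical(key1[sort(names(key1))], key2[sort(names(key2))])
  # labels follow first appearance in the (shuffled) input
  expect_identical(d2$samples$batch, match(d2$samples$batch_key,
                                           unique(d2$samples$batch_key)))
})

test_that("mixed dialects and missing identifiers are refused", {
  samples <- figure1_samples()
  samples$identifier_line[3] <- "@M1:5:1101:100:200#0/1"
  expect_error(infer_batches(samples), "mixed")
  samples$identifier_line[3] <- NA
  expect_error(infer_batches(samples), "missing identifier")
})

test_that("scan_identifier_lines flags a file mixing batch keys", {
  lines <- c("@M:1:FC:4:1101:1:1 1:N:0:AAAAAA",
             "@M:1:FC:4:1102:5:5 1:N:0:AAAAAA")
  expect_silent(scan_identifier_lines(lines))
  expect_error(scan_identifier_lines(c(lines, "@M:1:FC:5:1101:1:1 1:N:0:AAAAAA")),
               "mix")
})

test_that("the confounded layout yields 4 pure batches and high Cramer's V", {
  design <- infer_batches(figure1_samples())
  rep <- confounding_report(design, "species")
  expect_identical(rep$n_pure_batches, 4L)
  expect_equal(rep$purity, 22 / 26)   # all but the 4-sample mixed batch
  expect_false(rep$degenerate)
  expect_gt(rep$cramers_v, 0.9)
  expect_identical(unname(rowSums(rep$contingency)),
                   as.numeric(table(design$samples$batch)))
})

test_that("degenerate single-level tables report V = 1 with a flag", {
  one <- data.frame(sample_id = c("a", "b"), species = "human",
                    tissue = c("t1", "t2"),
                    identifier_line = rep("@M:1:FC:4:1:1:1 1:N:0:AAAAAA", 2))
  rep <- confounding_report(infer_batches(one), "species")
  expect_true(rep$degenerate)
  expect_identical(rep$cramers_v, 1)
  expect_equal(rep$purity, 1)
})

test_that("a balanced batch-by-factor table gives V = 0", {
  lines <- c("@M:1:FC:1:1:1:1 1:N:0:AAAAAA", "@M:1:FC:2:1:1:1 1:N:0:AAAAAA")
  samples <- data.frame(
    sample_id = paste0("s", 1:20),
    species = rep(rep(c("human", "mouse"), each = 5), 2),
    tissue = "t",
    identifier_line = rep(lines, each = 10))
  rep <- confounding_report(infer_batches(samples), "species")
  expect_equal(rep$cramers_v, 0)
  expect_identical(rep$n_pure_batches, 0L)
  expect_equal(rep$purity, 0)
})

test_that("purity is 1 iff every batch is single-level and drops strictly
          when a minority sample joins a pure batch", {
  samples <- figure1_samples()
  pure <- samples[samples$batch != 3L, ]
  rep_pure <- confounding_report(infer_batches(pure), "species")
  expect_equal(rep_pure$purity, 1)
  expect_identical(rep_pure$n_pure_batches, 4L)
  # move one mouse sample into the first (human) batch
  tainted <- pure
  tainted$identifier_line[tainted$sample_id == "mouse_tissue03"] <-
    tainted$identifier_line[tainted$sample_id == "human_tissue01"]
  rep_tainted <- confounding_report(infer_batches(tainted), "species")
  expect_lt(rep_tainted$purity, 1)
})
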