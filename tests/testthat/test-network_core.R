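test_that("partner list deduplicates via synonyms and keeps the first official symbol", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tdescription\tsynonyms",
               "TP53\ttumor protein p53\tBCC7,TRP53",
               "BCC7\tduplicate of TP53\t",
               "MDM2\tE3 ligase\tHDM2"), tf)
  p <- load_partner_list(tf)
  expect_equal(p$symbol, c("TP53", "MDM2"))
  expect_true("BCC7" %in% p$synonyms[[1L]])
})

test_that("partner list handles empty tables and disjoint rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("symbol\tdescription\tsynonyms", tf)
  expect_warning(p <- load_partner_list(tf), "empty")
  expect_equal(nrow(p), 0L)

  writeLines(c("symbol\tdescription\tsynonyms",
               "A\ta\tA1", "B\tb\tB1", "C\tc\t"), tf)
  expect_equal(nrow(load_partner_list(tf)), 3L)
})

test_that("synonym collisions between distinct official symbols warn and keep both", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tdescription\tsynonyms",
               "GENEA\t.\tSHARED",
               "GENEB\t.\tSHARED"), tf)
  expect_warning(p <- load_partner_list(tf), "collision")
  expect_equal(p$symbol, c("GENEA", "GENEB"))
})

test_that("missing required columns are named in the error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tdescription", "A\ta"), tf)
  expect_error(load_partner_list(tf), "synonyms")
})

test_that("BIOGRID parsing keeps only seed-partner rows as experimental evidence", {
  partners <- c("RDH10", "CYP26A1", "CYP26C1", "ADH5", "DHRS3", "ADH1B")
  expect_warning(
    edges <- parse_biogrid(extdata("synthetic_biogrid.tsv"), "ALDH1A2", partners),
    "self-edge")
  expect_setequal(edges$interactor_b, c("RDH10", "CYP26A1", "ADH5", "DHRS3"))
  expect_true(all(edges$channel == "experimental"))
  expect_true(all(edges$source == "biogrid"))
  expect_identical(attr(edges, "seed"), "ALDH1A2")
  # rows not touching the seed, or touching unknown partners, are dropped
  expect_false("GENEX" %in% edges$interactor_b)
})

test_that("STRING parsing emits one edge per channel above threshold", {
  partners <- c("RDH10", "CYP26A1", "CYP26C1", "ADH5", "DHRS3", "ADH1B")
  edges <- parse_string_links(extdata("synthetic_string_links.tsv"),
                              "ALDH1A2", partners,
                              id_map = extdata("synthetic_string_id_map.tsv"))
  byp <- split(edges$channel, edges$interactor_b)
  expect_setequal(byp$RDH10, "textmining")
  expect_setequal(byp$CYP26A1, c("coexpression", "database"))
  expect_setequal(byp$CYP26C1, "textmining")
  expect_setequal(byp$DHRS3, "textmining")
  expect_false("ADH5" %in% names(byp))   # all its scores below 400
  expect_true(all(edges$channel %in%
                    c("experimental", "database", "textmining", "coexpression")))
})

test_that("STRING threshold is validated and raising it removes edges", {
  partners <- c("RDH10", "CYP26A1")
  expect_error(parse_string_links(extdata("synthetic_string_links.tsv"),
                                  "ALDH1A2", partners, channel_threshold = 0),
               "0, 1000")
  expect_warning(
    e <- parse_string_links(extdata("synthetic_string_links.tsv"),
                            "ALDH1A2", partners, channel_threshold = 999,
                            id_map = extdata("synthetic_string_id_map.tsv")),
    "threshold")
  expect_equal(nrow(e), 0L)
})

test_that("STRING genomic-context channels count as database evidence only on opt-in", {
  partners <- "DHRS3"  # has cooccurence 120, textmining 450
  e1 <- parse_string_links(extdata("synthetic_string_links.tsv"),
                           "ALDH1A2", partners, channel_threshold = 100,
                           id_map = extdata("synthetic_string_id_map.tsv"))
  expect_setequal(e1$channel[e1$interactor_b == "DHRS3"], "textmining")
  e2 <- parse_string_links(extdata("synthetic_string_links.tsv"),
                           "ALDH1A2", partners, channel_threshold = 100,
                           id_map = extdata("synthetic_string_id_map.tsv"),
                           map_extra_channels = TRUE)
  expect_setequal(e2$channel[e2$interactor_b == "DHRS3"],
                  c("textmining", "database"))
})

test_that("a missing channel column is a format error", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 coexpression database combined_score",
               "9606.A 9606.B 100 100 100"), tf)
  expect_error(parse_string_links(tf, "A", "B"), "textmining")
})

test_that("evidence merging unions channels and is order-independent", {
  e1 <- rbind(
    data.frame(interactor_a = "S", interactor_b = "RDH10",
               channel = "experimental", source = "biogrid"),
    data.frame(interactor_a = "S", interactor_b = "RDH10",
               channel = "experimental", source = "string"),
    data.frame(interactor_a = "S", interactor_b = "RDH10",
               channel = "textmining", source = "string"),
    data.frame(interactor_a = "S", interactor_b = "ADH5",
               channel = "database", source = "string"))
  attr(e1, "seed") <- "S"
  m <- merge_evidence(e1)
  expect_equal(m$RDH10$channels, c("experimental", "textmining"))
  expect_equal(m$RDH10$sources, c("biogrid", "string"))
  expect_equal(length(m$ADH5$channels), 1L)

  set.seed(42)
  for (i in 1:10) {
    perm <- e1[sample(nrow(e1)), , drop = FALSE]
    attr(perm, "seed") <- "S"
    expect_identical(merge_evidence(perm), m)
  }
  expect_length(merge_evidence(e1[0, , drop = FALSE]), 0L)
})

test_that("contraction filters single-evidence partners and excludes the seed", {
  em <- list(A = list(partner = "A", channels = "textmining", sources = "string"),
             B = list(partner = "B", channels = c("experimental", "database"),
                      sources = c("biogrid", "string")),
             S = list(partner = "S", channels = c("experimental", "database",
                                                  "textmining"),
                      sources = "string"))
  core2 <- contract_network(em, seed = "S", min_channels = 2)
  expect_equal(core2$genes, "B")
  core1 <- contract_network(em, seed = "S", min_channels = 1)
  expect_equal(core1$genes, c("A", "B"))   # seed still excluded
  expect_error(contract_network(em, seed = "S", min_channels = 0), ">= 1")
  expect_warning(
    empty <- contract_network(em, seed = "S", min_channels = 4),
    "empty")
  expect_length(empty$genes, 0L)
})

test_that("contraction is monotone in the evidence threshold", {
  set.seed(7)
  for (rep in 1:20) {
    em <- lapply(sprintf("G%02d", 1:8), function(g) {
      list(partner = g,
           channels = sort(sample(c("experimental", "database", "textmining",
                                    "coexpression"), sample(1:4, 1))),
           sources = "string")
    })
    names(em) <- vapply(em, `[[`, "", "partner")
    prev <- contract_network(em, seed = "SEED", min_channels = 1)$genes
    for (k in 2:4) {
      cur <- suppressWarnings(
        contract_network(em, seed = "SEED", min_channels = k)$genes)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("the full contraction on the bundled fixtures yields the documented core", {
  p <- load_partner_list(extdata("synthetic_partner_list.tsv"))
  eb <- suppressWarnings(
    parse_biogrid(extdata("synthetic_biogrid.tsv"), "ALDH1A2", p$symbol))
  es <- parse_string_links(extdata("synthetic_string_links.tsv"),
                           "ALDH1A2", p$symbol,
                           id_map = extdata("synthetic_string_id_map.tsv"))
  edges <- rbind(eb, es)
  attr(edges, "seed") <- "ALDH1A2"
  core <- contract_network(merge_evidence(edges))
  expect_equal(core$genes, c("CYP26A1", "DHRS3", "RDH10"))
  expect_false(core$seed %in% core$genes)
  expect_false(any(duplicated(core$genes)))
})

test_that("provenance files round-trip to an identical core gene set", {
  p <- load_partner_list(extdata("synthetic_partner_list.tsv"))
  eb <- suppressWarnings(
    parse_biogrid(extdata("synthetic_biogrid.tsv"), "ALDH1A2", p$symbol))
  es <- parse_string_links(extdata("synthetic_string_links.tsv"),
                           "ALDH1A2", p$symbol,
                           id_map = extdata("synthetic_string_id_map.tsv"))
  edges <- rbind(eb, es)
  attr(edges, "seed") <- "ALDH1A2"
  core <- contract_network(merge_evidence(edges))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_provenance(core, tf)
  back <- read_provenance(tf)
  expect_equal(back, core, ignore_attr = FALSE)
})
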