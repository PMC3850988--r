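write_hits <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_hits <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s1", "s3", "s1"),
    peptide = c("AAAK", "AAAK", "CCCK", "DDDK", "AAAK"),
    entry_id = c("E1", "E1", "E2", "E3", "E1"),
    evalue = c(0.01, 0.05, 0.2, 0.001, 0.02),
    stringsAsFactors = FALSE
  )
}

test_that("hit loading validates columns, e-values and entry references", {
  p <- write_hits(toy_hits())
  hits <- load_hits(p)
  expect_equal(nrow(hits), 5L)

  entries <- data.frame(entry_id = c("E1", "E2"), peptide = c("AAAK", "CCCK"),
                        stringsAsFactors = FALSE)
  expect_message(hits2 <- load_hits(p, entries), "unknown entry ids")
  expect_equal(nrow(hits2), 4L)

  bad <- toy_hits(); bad$evalue[1] <- -1
  expect_message(hits3 <- load_hits(write_hits(bad)), "non-positive")
  expect_equal(nrow(hits3), 4L)

  noev <- toy_hits(); noev$evalue <- NULL
  expect_error(load_hits(write_hits(noev)), "evalue")
})

test_that("e-value filtering is monotone in the cutoff", {
  hits <- toy_hits()
  expect_equal(nrow(filter_evalue(hits, 0.1)), 4L)
  expect_equal(nrow(filter_evalue(hits, Inf)), 5L)
  expect_equal(nrow(filter_evalue(hits, 1e-9)), 0L)
  prev <- -1L
  for (cut in c(0.001, 0.02, 0.05, 0.2)) {
    n <- nrow(filter_evalue(hits, cut))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("minimum-sample filtering counts distinct samples and is antitone in n", {
  hits <- toy_hits()  # AAAK seen in s1 (twice) and s2; others once
  expect_setequal(filter_min_samples(hits, 2), "AAAK")
  expect_setequal(filter_min_samples(hits, 1),
                  c("AAAK", "CCCK", "DDDK"))
  expect_length(filter_min_samples(hits, 3), 0L)
  for (n in 1:4) {
    expect_true(all(filter_min_samples(hits, n + 1) %in%
                      filter_min_samples(hits, n)))
  }
})

test_that("novelty is scoped to the source gene and invariant to unrelated proteins", {
  prot <- Biostrings::AAStringSet(c(
    "MKAAAKLLLVVV",      # gene GA protein containing AAAK
    "MWWWWCCCKWWW"))     # unrelated gene GB protein containing CCCK
  names(prot) <- c("P1 gene=GA", "P2 gene=GB")

  n1 <- check_novelty("AAAK", "GA", prot)
  expect_false(n1$novel)          # present verbatim in its own gene
  n2 <- check_novelty("CCCK", "GA", prot)
  expect_true(n2$novel)           # only an unrelated gene carries it
  expect_true(n2$global_hit)
  n3 <- check_novelty("CCCK", "GA", prot, scope = "global")
  expect_false(n3$novel)

  # adding more unrelated proteins cannot change a gene-scope call
  bigger <- c(prot, Biostrings::AAStringSet(stats::setNames("MAAAKCCCK", "P3 gene=GC")))
  expect_equal(check_novelty("CCCK", "GA", bigger)$novel, n2$novel)

  expect_warning(n4 <- check_novelty("AAAK", "GZ", prot), "absent")
  expect_true(n4$novel)

  # I/L collapse: peptide differing only by I<->L matches when enabled
  expect_true(check_novelty("AAIK", "GA", Biostrings::AAStringSet(
    stats::setNames("MAALKM", "P gene=GA")))$novel)
  expect_false(check_novelty("AAIK", "GA", Biostrings::AAStringSet(
    stats::setNames("MAALKM", "P gene=GA")), collapse_il = TRUE)$novel)
})

test_that("junction peptides absent from the normal-splicing proteome are novel", {
  r <- local({
    fx <- default_fixture(seed = 7, dir = withr::local_tempdir())
    ann <- load_annotation(fx$annotation_path, fx$genome_path)
    build_database(ann$models, ann$genome)
  })
  prot <- normal_splicing_proteome(r$entries)
  skip_pep <- r$entries$peptide[r$entries$type == "E_E_AS"][1]
  expect_true(check_novelty(skip_pep, "GENE001", prot)$novel)
  nm_pep <- r$entries$peptide[r$entries$type == "EXON_NM"][1]
  expect_false(check_novelty(nm_pep, "GENE001", prot)$novel)
})

test_that("exact rank-sum p-values match the permutation oracle on 5v5 designs", {
  groups <- data.frame(sample_id = c(paste0("c", 1:5), paste0("k", 1:5)),
                       group = rep(c("control", "case"), each = 5))
  # peptide present in all cases, no controls: p = 1/choose(10,5)
  hits <- data.frame(sample_id = paste0("k", 1:5), peptide = "PEP",
                     entry_id = "E", evalue = 0.01, stringsAsFactors = FALSE)
  res <- differential_presence(hits, groups)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$h, 0L)
  expect_equal(res$c, 5L)
  expect_equal(res$direction, "up_in_case")

  # a scatter of (h, c) configurations against the independent U oracle
  for (h in c(0L, 1L, 3L, 5L)) {
    for (cc in c(0L, 2L, 4L, 5L)) {
      x_case <- c(rep(1, cc), rep(0, 5 - cc))
      x_ctrl <- c(rep(1, h), rep(0, 5 - h))
      hh <- do.call(rbind, c(
        lapply(which(x_ctrl == 1), function(i) data.frame(
          sample_id = paste0("c", i), peptide = "P", entry_id = "E",
          evalue = 0.01)),
        lapply(which(x_case == 1), function(i) data.frame(
          sample_id = paste0("k", i), peptide = "P", entry_id = "E",
          evalue = 0.01))))
      if (is.null(hh)) next
      got <- differential_presence(hh, groups)$p_value
      want <- perm_rank_oracle(x_case, x_ctrl)
      expect_equal(got, want, tolerance = 1e-12,
                   info = sprintf("h=%d c=%d", h, cc))
    }
  }
})

test_that("identical presence vectors are degenerate with p = 1", {
  groups <- data.frame(sample_id = c(paste0("c", 1:3), paste0("k", 1:3)),
                       group = rep(c("control", "case"), each = 3))
  hits <- data.frame(sample_id = c(paste0("c", 1:3), paste0("k", 1:3)),
                     peptide = "P", entry_id = "E", evalue = 0.01,
                     stringsAsFactors = FALSE)
  res <- differential_presence(hits, groups)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("large designs fall back to the tie-corrected normal approximation", {
  set.seed(30)
  groups <- data.frame(sample_id = c(paste0("c", 1:20), paste0("k", 1:20)),
                       group = rep(c("control", "case"), each = 20))
  present <- c(paste0("c", 1:2), paste0("k", 1:15))
  hits <- data.frame(sample_id = present, peptide = "P", entry_id = "E",
                     evalue = 0.01, stringsAsFactors = FALSE)
  res <- differential_presence(hits, groups)
  ref <- suppressWarnings(stats::wilcox.test(
    c(rep(1, 15), rep(0, 5)), c(rep(1, 2), rep(0, 18)),
    alternative = "greater", exact = FALSE, correct = TRUE)$p.value)
  expect_equal(res$p_value, ref, tolerance = 1e-12)
})

test_that("marker calling applies alpha and optional Benjamini-Hochberg", {
  res <- data.frame(peptide = paste0("P", 1:4), entry_id = paste0("E", 1:4),
                    h = 0L, c = 3L,
                    p_value = c(0.001, 0.03, 0.04, 0.2),
                    direction = "up_in_case", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(call_markers(res, alpha = 0.05)$peptide, c("P1", "P2", "P3"))
  expect_equal(nrow(call_markers(res, alpha = 0)), 0L)
  bh <- call_markers(res, alpha = 0.05, adjust = "BH")
  # hand-computed BH: 0.004, 0.0533..., 0.0533..., 0.2
  expect_equal(bh$peptide, "P1")
  expect_equal(bh$p_adjusted, 0.004)
})

test_that("signed-rank testing demands an explicit pairing", {
  groups <- data.frame(sample_id = c(paste0("c", 1:3), paste0("k", 1:3)),
                       group = rep(c("control", "case"), each = 3))
  hits <- data.frame(sample_id = "k1", peptide = "P", entry_id = "E",
                     evalue = 0.01, stringsAsFactors = FALSE)
  expect_error(differential_presence(hits, groups, method = "signed_rank"),
               "pairing")
})

test_that("end-to-end: a planted skipped-exon peptide is the sole novel marker", {
  dir <- withr::local_tempdir()
  fx <- default_fixture(seed = 7, dir = dir)
  ann <- load_annotation(fx$annotation_path, fx$genome_path)
  db <- build_database(ann$models, ann$genome)
  prot <- normal_splicing_proteome(db$entries)

  # plant: one exon-skip peptide present in all case samples and no
  # controls; everything else present everywhere (uninformative)
  target <- which(db$entries$type == "E_E_AS")[1]
  pm <- matrix(1, nrow = nrow(db$entries), ncol = 2)
  pm[target, ] <- c(0, 1)
  hits <- generate_hit_table(db$entries, n_samples_per_group = 5,
                             presence = pm, seed = 41)
  groups <- unique(hits[c("sample_id", "group")])

  markers <- run_marker_analysis(hits, db$entries, groups,
                                 proteome = prot, require_novel = TRUE)
  expect_equal(nrow(markers), 1L)
  expect_equal(markers$entry_id, db$entries$entry_id[target])
  expect_equal(markers$type, "E_E_AS")
  expect_true(markers$novel)
  expect_equal(markers$h, 0L)
  expect_equal(markers$c, 5L)
  expect_equal(markers$p_value, 1 / choose(10, 5), tolerance = 1e-12)
})
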