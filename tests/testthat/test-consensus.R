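sp <- c("Spu", "Pmi")

# Build a normalized_output directly from gene pairs / clusters.
mk_norm <- function(tool, pairs, clusters = list()) {
  groups <- c(
    lapply(seq_len(nrow(pairs)), function(i) {
      list(tool = tool, group_id = sprintf("P%03d", i), level = "gene",
           members = data.frame(species = sp, gene = c(pairs$gene_a[i], pairs$gene_b[i]),
                                stringsAsFactors = FALSE),
           flags = list(is_candidate_1to1 = TRUE, has_coorthologs = FALSE))
    }),
    lapply(seq_along(clusters), function(i) {
      m <- clusters[[i]]
      list(tool = tool, group_id = sprintf("C%03d", i), level = "gene",
           members = m, flags = list(is_candidate_1to1 = FALSE, has_coorthologs = TRUE))
    }))
  structure(list(tool = tool, species_pair = sp, groups = groups,
                 audit = list()), class = "normalized_output")
}

pair_df <- function(a, b) data.frame(gene_a = as.integer(a), gene_b = as.integer(b))

test_that("a tool votes only for exact two-member, two-species groups", {
  outs <- list(
    mk_norm("oma", pair_df(1, 10)),
    mk_norm("orthofinder", pair_df(1, 10),
            clusters = list(data.frame(species = c("Spu", "Pmi", "Pmi"),
                                       gene = c(2L, 11L, 12L)))),
    mk_norm("swiftortho", pair_df(integer(), integer()),
            clusters = list(data.frame(species = c("Spu", "Spu"),
                                       gene = c(1L, 3L)))))
  v <- vote_pairs(outs)
  expect_equal(nrow(v), 1L)
  expect_equal(sort(v$tools[[1]]), c("oma", "orthofinder"))
  expect_equal(nrow(vote_pairs(list())), 0L)
  expect_error(vote_pairs(list(mk_norm("oma", pair_df(1, 10)),
                               mk_norm("oma", pair_df(1, 10)))), "duplicate tool")
})

test_that("call_consensus applies the k threshold inclusively", {
  outs <- lapply(all_tools[1:4], mk_norm, pairs = pair_df(1, 10))
  outs <- c(outs, lapply(all_tools[5:6], mk_norm, pairs = pair_df(2, 11)))
  v <- vote_pairs(outs)
  calls3 <- call_consensus(v, consensus_config(k = 3))
  expect_equal(calls3$gene_a, 1L)
  expect_equal(calls3$n_support, 4L)
  calls1 <- call_consensus(v, consensus_config(k = 1))
  expect_equal(nrow(calls1), 2L)
  expect_error(consensus_config(k = 7), "k must satisfy")
  expect_error(consensus_config(k = 0), "k must satisfy")
})

test_that("conflicting above-threshold pairs resolve by votes, ties drop", {
  outs <- c(lapply(all_tools[1:4], mk_norm, pairs = pair_df(1, 10)),
            lapply(all_tools[5:6], function(t) mk_norm(t, pair_df(c(1, 2), c(11, 12)))))
  # (1,10) has 4 votes, (1,11) has 2: below k=3, no conflict; at k=2 conflict
  v <- vote_pairs(outs)
  calls <- call_consensus(v, consensus_config(k = 2))
  expect_equal(calls$gene_b[calls$gene_a == 1L], 10L)
  expect_equal(attr(calls, "n_conflicts"), 1L)
  # both sides stay unique: partial bijection
  expect_false(anyDuplicated(calls$gene_a) > 0)
  expect_false(anyDuplicated(calls$gene_b) > 0)
})

test_that("conflict handling matches the brute-force max-vote oracle", {
  set.seed(91)
  for (rep in 1:30) {
    n_pairs <- sample(3:10, 1)
    pairs <- unique(data.frame(gene_a = sample(1:5, n_pairs, replace = TRUE),
                               gene_b = sample(11:15, n_pairs, replace = TRUE)))
    n_votes <- sample(1:6, nrow(pairs), replace = TRUE)
    outs <- lapply(seq_along(all_tools), function(ti) {
      sel <- n_votes >= ti   # pair i voted by tools 1..n_votes[i]
      mk_norm(all_tools[ti], pairs[sel, , drop = FALSE])
    })
    k <- sample(1:4, 1)
    calls <- call_consensus(vote_pairs(outs), consensus_config(k = k))
    want <- oracle_consensus(cbind(pairs, n = n_votes), k)
    expect_equal(calls$gene_a, want$gene_a, label = paste("rep", rep))
    expect_equal(calls$gene_b, want$gene_b, label = paste("rep", rep))
    expect_equal(calls$n_support, want$n, label = paste("rep", rep))
  }
})

test_that("calls are monotone in k and invariant under shuffling", {
  truth <- generate_truth(40, 10, 0, 10, seed = 5)
  rendered <- render_tool_outputs(truth, noise_model(p_drop = 0.35))
  maps <- idmaps_from_truth(truth)
  outs <- lapply(rendered$tool_outputs, to_gene_level, idmaps = maps)
  v <- vote_pairs(unname(outs))
  key <- function(calls) paste(calls$gene_a, calls$gene_b)
  prev <- NULL
  for (k in 6:1) {
    calls <- call_consensus(v, consensus_config(k = k))
    if (!is.null(prev)) expect_true(all(prev %in% key(calls)), label = paste("k", k))
    prev <- key(calls)
  }
  # shuffle tool order and group order within tools
  set.seed(17)
  outs2 <- lapply(sample(unname(outs)), function(o) { o$groups <- sample(o$groups); o })
  calls_a <- call_consensus(vote_pairs(unname(outs)), consensus_config(k = 3))
  calls_b <- call_consensus(vote_pairs(outs2), consensus_config(k = 3))
  expect_identical(key(calls_a), key(calls_b))
  expect_identical(calls_a$supporting_tools, calls_b$supporting_tools)
})

test_that("consensus_pipeline recovers a planted map and enforces k-feasibility", {
  truth <- generate_truth(15, 0, 0, 5, seed = 2)
  rendered <- render_tool_outputs(truth)
  maps <- idmaps_from_truth(truth)
  res <- consensus_pipeline(rendered$tool_outputs, truth$species_pair, maps)
  sc <- score_recovery(res$calls, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(res$audit$n_calls, 15L)

  # three identical outputs at k=3: calls equal that output's candidate set
  three <- rendered$tool_outputs[1:3]
  res3 <- consensus_pipeline(three, truth$species_pair, maps)
  expect_equal(nrow(res3$calls), 15L)
  expect_error(consensus_pipeline(rendered$tool_outputs[1:2], truth$species_pair,
                                  maps, cfg = consensus_config(k = 3)),
               "never be reached")
})

test_that("consensus TSV round-trips with deterministic ordering", {
  truth <- generate_truth(8, 0, 0, 0, seed = 12)
  rendered <- render_tool_outputs(truth)
  res <- consensus_pipeline(rendered$tool_outputs, truth$species_pair,
                            idmaps_from_truth(truth))
  lines1 <- write_consensus_tsv(res$calls)
  rt <- read_consensus_tsv(lines1)
  expect_equal(rt$gene_a, res$calls$gene_a)
  expect_equal(rt$n_support, res$calls$n_support)
  expect_identical(attr(rt, "species_pair"), attr(res$calls, "species_pair"))
  expect_identical(write_consensus_tsv(res$calls), lines1)
})
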