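sp <- c("Spu", "Pmi")

mk_group <- function(species, ids, id = "G1", tool = "oma") {
  ortho_group(tool, id, data.frame(species = species, id = ids,
                                   stringsAsFactors = FALSE))
}

mk_idmaps <- function(acc_a, gene_a, acc_b, gene_b) {
  list(Spu = idmap("Spu", acc_a, gene_a, "gtf"),
       Pmi = idmap("Pmi", acc_b, gene_b, "gtf"))
}

test_that("single-species groups are filtered, order preserved", {
  g1 <- mk_group("Spu", "XP_000000001.1", "A")
  g2 <- mk_group(c("Spu", "Pmi"), c("XP_000000001.1", "XP_000000101.1"), "B")
  fs <- filter_single_species(list(g1, g2))
  expect_length(fs$kept, 1L)
  expect_equal(fs$kept[[1]]$group_id, "B")
  expect_equal(fs$n_removed, 1L)
  expect_equal(filter_single_species(list()), list(kept = list(), n_removed = 0L))
  fs2 <- filter_single_species(list(g2))
  expect_equal(fs2$n_removed, 0L)
})

test_that("strip_to_refseq extracts the first RefSeq accession, NA otherwise", {
  expect_equal(strip_to_refseq("sp|XP_000000001.1|SOMEGENE"), "XP_000000001.1")
  expect_equal(strip_to_refseq("XP_000000002.1_Aplanci"), "XP_000000002.1")
  expect_true(is.na(strip_to_refseq("scaffold_441.12")))
  expect_equal(strip_to_refseq(c("NP_001.2", "x")), c("NP_001.2", NA))
})

test_that("to_gene_level collapses proteins to genes and flags candidates", {
  maps <- mk_idmaps(c("XP_000000001.1", "XP_000000002.1"), c(101L, 101L),
                    c("XP_000000101.1", "XP_000000102.1"), c(201L, 202L))
  # two Spu proteins of one gene + one Pmi protein -> clean 1:1 candidate
  out <- tool_output("oma", sp, list(
    mk_group(c("Spu", "Spu", "Pmi"),
             c("XP_000000001.1", "XP_000000002.1", "XP_000000101.1"))))
  n <- to_gene_level(out, maps)
  expect_length(n$groups, 1L)
  g <- n$groups[[1]]
  expect_equal(sort(paste(g$members$species, g$members$gene)),
               c("Pmi 201", "Spu 101"))
  expect_true(g$flags$is_candidate_1to1)
  expect_false(g$flags$has_coorthologs)

  # two distinct Pmi genes -> co-orthologs, not a 1:1 candidate
  out2 <- tool_output("oma", sp, list(
    mk_group(c("Spu", "Pmi", "Pmi"),
             c("XP_000000001.1", "XP_000000101.1", "XP_000000102.1"))))
  g2 <- to_gene_level(out2, maps)$groups[[1]]
  expect_true(g2$flags$has_coorthologs)
  expect_false(g2$flags$is_candidate_1to1)
})

test_that("groups becoming single-species after mapping losses are refiltered", {
  maps <- mk_idmaps("XP_000000001.1", 101L, "XP_000000101.1", 201L)
  out <- tool_output("oma", sp, list(
    mk_group(c("Spu", "Pmi"), c("XP_000000001.1", "XP_000000999.1"))))
  n <- to_gene_level(out, maps)
  expect_length(n$groups, 0L)
  expect_equal(n$audit$ids_unmapped, 1L)
  expect_equal(n$audit$single_species_filtered, 1L)
  # oracle: the same cascade with refilter off keeps the one-species remnant
  n2 <- to_gene_level(out, maps, refilter = FALSE)
  expect_length(n2$groups, 1L)
  # strict mode aborts instead of dropping
  expect_error(to_gene_level(out, maps, strict = TRUE), "XP_000000999.1")
})

test_that("collapse_duplicates merges overlapping groups transitively", {
  gg <- function(id, species, gene) {
    list(tool = "t", group_id = id, level = "gene",
         members = data.frame(species = species, gene = as.integer(gene),
                              stringsAsFactors = FALSE))
  }
  merged <- collapse_duplicates(list(
    gg("A", c("Spu", "Pmi"), c(1, 10)), gg("B", c("Spu", "Pmi"), c(1, 11))))
  expect_length(merged, 1L)
  expect_equal(sort(paste(merged[[1]]$members$species, merged[[1]]$members$gene)),
               c("Pmi 10", "Pmi 11", "Spu 1"))
  expect_equal(merged[[1]]$group_id, "A")
  expect_equal(attr(merged, "n_merged"), 1L)

  disjoint <- list(gg("A", c("Spu", "Pmi"), c(1, 10)), gg("B", c("Spu", "Pmi"), c(2, 11)))
  expect_length(collapse_duplicates(disjoint), 2L)

  # chain A~B, B~C with A,C disjoint: all three merge (6-group instance)
  chain <- list(gg("A", c("Spu", "Pmi"), c(1, 10)), gg("B", c("Spu", "Pmi"), c(1, 11)),
                gg("C", c("Spu", "Pmi"), c(2, 11)), gg("D", c("Spu", "Pmi"), c(3, 12)),
                gg("E", c("Spu", "Pmi"), c(4, 13)), gg("F", c("Spu", "Pmi"), c(4, 12)))
  got <- gene_group_signatures(collapse_duplicates(chain))
  want <- oracle_transitive_merge(lapply(chain, function(g) {
    paste(g$members$species, g$members$gene)
  }))
  expect_identical(got, sort(vapply(want, function(s) paste(sort(s), collapse = ";"),
                                    character(1))))
})

test_that("collapse_duplicates matches the brute-force closure on random instances", {
  for (seed in 1:60) {
    groups <- random_gene_groups(n_groups = 10L, gene_pool = 12L, seed = seed)
    got <- collapse_duplicates(groups)
    want <- oracle_transitive_merge(lapply(groups, function(g) {
      paste(g$members$species, g$members$gene)
    }))
    expect_identical(gene_group_signatures(got),
                     sort(vapply(want, function(s) paste(sort(s), collapse = ";"),
                                 character(1))),
                     label = paste("seed", seed))
    # idempotence and the once-per-output invariant
    expect_identical(gene_group_signatures(collapse_duplicates(got)),
                     gene_group_signatures(got))
    keys <- unlist(lapply(got, function(g) paste(g$members$species, g$members$gene)))
    expect_false(anyDuplicated(keys) > 0)
    # order independence
    set.seed(seed + 5000)
    shuffled <- collapse_duplicates(sample(groups))
    expect_identical(gene_group_signatures(shuffled), gene_group_signatures(got))
  }
})

test_that("normalized outputs satisfy the once-per-output invariant end to end", {
  truth <- generate_truth(20, 5, 5, 5, seed = 33)
  rendered <- render_tool_outputs(truth, noise_model(p_merge = 0.4, p_split = 0.3,
                                                     p_decorate = 0.3))
  maps <- idmaps_from_truth(truth)
  for (tool in all_tools) {
    n <- to_gene_level(rendered$tool_outputs[[tool]], maps)
    keys <- unlist(lapply(n$groups, function(g) paste(g$members$species, g$members$gene)))
    expect_false(anyDuplicated(keys) > 0, label = tool)
    expect_equal(n$audit$groups_out, length(n$groups))
    # flag equivalence with a brute-force per-species gene counter
    for (g in n$groups) {
      per_sp <- table(g$members$species)
      expect_equal(g$flags$is_candidate_1to1,
                   length(per_sp) == 2L && all(per_sp == 1L))
      expect_equal(g$flags$has_coorthologs, any(per_sp >= 2L))
    }
  }
})

test_that("normalized TSV serialization carries flags and members", {
  maps <- mk_idmaps("XP_000000001.1", 101L, "XP_000000101.1", 201L)
  out <- tool_output("oma", sp, list(
    mk_group(c("Spu", "Pmi"), c("XP_000000001.1", "XP_000000101.1"))))
  lines <- write_normalized_tsv(to_gene_level(out, maps))
  expect_match(lines[1], "^tool\tgroup_id")
  expect_equal(length(lines), 3L)
  expect_match(lines[2], "oma\tG1\t(Spu\t101|Pmi\t201)\tTRUE\tFALSE")
})
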