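# Independent oracles and fixture helpers shared across the suite.
# Oracles are deliberately written as naive brute-force procedures, not by
# reusing the package's own implementations.

# Canonical signature of a tool output's groups: sorted member-set strings.
group_signatures <- function(o) {
  sort(vapply(o$groups, function(g) {
    paste(sort(paste(g$members$species, g$members$id)), collapse = ";")
  }, character(1)))
}

gene_group_signatures <- function(groups) {
  sort(vapply(groups, function(g) {
    paste(sort(paste(g$members$species, g$members$gene)), collapse = ";")
  }, character(1)))
}

# Brute-force transitive closure: repeatedly merge any two sets that overlap
# until a fixed point is reached.
oracle_transitive_merge <- function(sets) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) return(sets)
  }
}

# Brute-force 1:1 selection: a pair survives iff it is the unique vote
# maximum among all above-threshold pairs sharing its gene on either side.
oracle_consensus <- function(pairs, k) {
  # pairs: data.frame(gene_a, gene_b, n)
  keep <- pairs[pairs$n >= k, , drop = FALSE]
  ok <- vapply(seq_len(nrow(keep)), function(i) {
    rival_a <- keep[keep$gene_a == keep$gene_a[i], , drop = FALSE]
    rival_b <- keep[keep$gene_b == keep$gene_b[i], , drop = FALSE]
    unique_max <- function(r) {
      sum(r$n == max(r$n)) == 1L && keep$n[i] == max(r$n)
    }
    unique_max(rival_a) && unique_max(rival_b)
  }, logical(1))
  out <- keep[ok, , drop = FALSE]
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# Brute-force nested-loop composition of two anchor maps.
oracle_lateral_join <- function(pairs_xa, pairs_ya) {
  out_x <- integer(); out_y <- integer()
  for (i in seq_len(nrow(pairs_xa))) {
    for (j in seq_len(nrow(pairs_ya))) {
      if (pairs_xa$gene_a[i] == pairs_ya$gene_a[j]) {
        out_x <- c(out_x, pairs_xa$gene_b[i])
        out_y <- c(out_y, pairs_ya$gene_b[j])
      }
    }
  }
  ord <- order(out_x, out_y)
  data.frame(gene_a = out_x[ord], gene_b = out_y[ord])
}

# Random protein-level tool output over a fixed species pair.
random_tool_output <- function(tool, seed, species_pair = c("Spu", "Pmi")) {
  set.seed(seed)
  n <- sample(1:6, 1L)
  groups <- lapply(seq_len(n), function(i) {
    m <- sample(1:4, 1L)
    ortho_group(tool, sprintf("G%03d", i),
                data.frame(species = sample(species_pair, m, replace = TRUE),
                           id = sprintf("XP_%09d.1", sample.int(1e6, m)),
                           stringsAsFactors = FALSE))
  })
  tool_output(tool, species_pair, groups)
}

# Random gene-level groups (plain lists, the shape collapse_duplicates takes).
random_gene_groups <- function(n_groups, gene_pool = 15L, seed = 1L,
                               species_pair = c("Spu", "Pmi")) {
  set.seed(seed)
  lapply(seq_len(n_groups), function(i) {
    m <- sample(2:4, 1L)
    members <- unique(data.frame(
      species = sample(species_pair, m, replace = TRUE),
      gene = sample.int(gene_pool, m, replace = TRUE),
      stringsAsFactors = FALSE))
    list(tool = "test", group_id = sprintf("G%03d", i), members = members,
         level = "gene")
  })
}

# Idmaps straight from a ground truth's protein table (bypasses GTF/GPFF).
idmaps_from_truth <- function(truth) {
  out <- lapply(truth$species_pair, function(s) {
    pt <- truth$protein_table[truth$protein_table$species == s, , drop = FALSE]
    idmap(s, pt$accession, pt$gene, source = "gtf")
  })
  names(out) <- truth$species_pair
  out
}

all_tools <- c("orthofinder", "proteinortho", "inparanoid", "oma",
               "swiftortho", "fastortho")
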