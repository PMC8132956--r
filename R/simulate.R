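#' Generate a planted ground-truth ortholog scenario
#'
#' Builds a deterministic, seeded ground truth for a species pair containing
#' the relation categories the consensus pipeline must handle: clean 1:1
#' orthologs, many:1 and many:many co-ortholog clusters, and unassigned genes
#' with no cross-species relation. Every gene carries one or more synthetic
#' RefSeq protein accessions (`"XP_" +` zero-padded integer `+ ".1"`),
#' globally unique, so fixtures traverse the same accession validation as
#' real data; multiple accessions per gene exercise the many-proteins-to-one-
#' gene collapse.
#'
#' @param n_one2one,n_many2one,n_many2many Number of relations per category.
#'   Many:1 relations place 2-3 genes in the first species against one in the
#'   second; many:many 2-3 against 2-3.
#' @param n_unassigned Number of genes (alternating species) in no relation.
#' @param proteins_per_gene_max Each gene receives 1..max accessions
#'   (uniformly; default 2).
#' @param seed RNG seed; identical seeds give identical truths.
#' @param species_pair Ordered pair of species tags.
#' @return A `ground_truth`: `species_pair`, `genes_a`, `genes_b`,
#'   `relations` (list of `list(category, genes_a, genes_b)`),
#'   `protein_table` (data frame `species`, `gene`, `accession`), `seed`.
#' @export
generate_truth <- function(n_one2one = 100L, n_many2one = 0L, n_many2many = 0L,
                           n_unassigned = 0L, proteins_per_gene_max = 2L,
                           seed = 1L, species_pair = c("Spu", "Pmi")) {
  stopifnot(n_one2one >= 0, n_many2one >= 0, n_many2many >= 0,
            n_unassigned >= 0, proteins_per_gene_max >= 1)
  .with_seed(seed, {
    next_a <- 100000L; next_b <- 200000L; next_p <- 0L
    genes_a <- integer(); genes_b <- integer()
    new_genes <- function(side, n) {
      if (side == "a") {
        ids <- next_a + seq_len(n); next_a <<- next_a + n
        genes_a <<- c(genes_a, ids)
      } else {
        ids <- next_b + seq_len(n); next_b <<- next_b + n
        genes_b <<- c(genes_b, ids)
      }
      ids
    }
    relations <- list()
    add_rel <- function(category, na, nb) {
      relations[[length(relations) + 1L]] <<-
        list(category = category,
             genes_a = if (na) new_genes("a", na) else integer(),
             genes_b = if (nb) new_genes("b", nb) else integer())
    }
    for (i in seq_len(n_one2one)) add_rel("one2one", 1L, 1L)
    for (i in seq_len(n_many2one)) add_rel("many2one", sample(2:3, 1L), 1L)
    for (i in seq_len(n_many2many)) add_rel("many2many", sample(2:3, 1L), sample(2:3, 1L))
    for (i in seq_len(n_unassigned)) {
      if (i %% 2L == 1L) new_genes("a", 1L) else new_genes("b", 1L)
    }
    all_genes <- data.frame(
      species = c(rep(species_pair[1L], length(genes_a)),
                  rep(species_pair[2L], length(genes_b))),
      gene = c(genes_a, genes_b), stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(all_genes)), function(i) {
      np <- sample.int(proteins_per_gene_max, 1L)
      acc <- sprintf("XP_%09d.1", next_p + seq_len(np))
      next_p <<- next_p + np
      data.frame(species = all_genes$species[i], gene = all_genes$gene[i],
                 accession = acc, stringsAsFactors = FALSE)
    })
    structure(list(species_pair = species_pair, genes_a = genes_a,
                   genes_b = genes_b, relations = relations,
                   protein_table = do.call(rbind, rows), seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cats <- table(vapply(x$relations, `[[`, character(1), "category"))
  cat("<ground_truth>", paste(x$species_pair, collapse = " vs "), "-",
      length(x$genes_a), "+", length(x$genes_b), "genes,",
      nrow(x$protein_table), "proteins; relations:",
      paste(names(cats), cats, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' The planted 1:1 gene pairs of a ground truth
#' @param truth A `ground_truth`.
#' @return Data frame `gene_a`, `gene_b` (one row per one2one relation).
#' @export
truth_one2one_pairs <- function(truth) {
  one <- Filter(function(r) r$category == "one2one", truth$relations)
  data.frame(gene_a = vapply(one, function(r) r$genes_a, integer(1)),
             gene_b = vapply(one, function(r) r$genes_b, integer(1)))
}

#' Noise model for fixture rendering
#'
#' Structural noise applied independently per tool: each group is omitted
#' with probability `p_drop`; consecutive surviving groups are merged with
#' probability `p_merge`; a group with three or more members is split in two
#' with probability `p_split`; each emitted identifier is decorated (FASTA
#' header prefixes, species suffixes) with probability `p_decorate`. Noise
#' acts on group structure and token text only, never on sequences.
#'
#' @param p_drop,p_merge,p_split,p_decorate Probabilities in `[0, 1]`.
#' @return A `noise_model`.
#' @export
noise_model <- function(p_drop = 0, p_merge = 0, p_split = 0, p_decorate = 0) {
  p <- c(p_drop, p_merge, p_split, p_decorate)
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(p_drop = p_drop, p_merge = p_merge, p_split = p_split,
                 p_decorate = p_decorate),
            class = "noise_model")
}

# Per-tool seeds from the master seed: seed_i = (master + 7919 * i) mod 2^31-1.
.tool_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + 7919 * i) %% 2147483647)
}

.decorate_id <- function(id, species) {
  style <- sample.int(3L, length(id), replace = TRUE)
  out <- id
  out[style == 1L] <- paste0("sp|", id[style == 1L], "|GENE")
  out[style == 2L] <- paste0(id[style == 2L], "_", species[style == 2L])
  out[style == 3L] <- paste0("lcl|", id[style == 3L])
  out
}

#' Render a ground truth into all six tool-output dialects
#'
#' At zero noise every cross-species relation appears in every tool output as
#' one protein-level group holding the accessions of all its genes;
#' unassigned genes appear in no group. GTF and GPFF fragments carrying
#' exactly the protein-to-gene keys of the truth's protein table are rendered
#' per species.
#'
#' @param truth A [generate_truth()] result.
#' @param noise A [noise_model()].
#' @param master_seed Master seed for the per-tool noise streams (defaults to
#'   the truth's seed).
#' @return List with `tool_outputs` (named list of six [tool_output()]s),
#'   `gtf` and `gpff` (named-by-species lists of text lines).
#' @export
render_tool_outputs <- function(truth, noise = noise_model(),
                                master_seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_model"))
  sp <- truth$species_pair
  pt <- truth$protein_table
  base_groups <- lapply(truth$relations, function(r) {
    sel <- pt$gene %in% c(r$genes_a, r$genes_b)
    .members_df(pt$species[sel], pt$accession[sel])
  })
  cross <- vapply(truth$relations, function(r) {
    length(r$genes_a) > 0L && length(r$genes_b) > 0L
  }, logical(1))
  base_groups <- base_groups[cross]

  tool_outputs <- lapply(seq_along(.tool_tags), function(i) {
    tool <- .tool_tags[i]
    .with_seed(.tool_seed(master_seed, i), {
      members <- base_groups
      if (noise$p_drop > 0 && length(members)) {
        members <- members[stats::runif(length(members)) >= noise$p_drop]
      }
      if (noise$p_split > 0 && length(members)) {
        out <- list()
        for (m in members) {
          if (nrow(m) >= 3L && stats::runif(1) < noise$p_split) {
            cut <- sample(seq_len(nrow(m) - 1L), 1L)
            out <- c(out, list(m[seq_len(cut), , drop = FALSE],
                               m[(cut + 1L):nrow(m), , drop = FALSE]))
          } else out <- c(out, list(m))
        }
        members <- out
      }
      if (noise$p_merge > 0 && length(members) > 1L) {
        out <- list(members[[1L]])
        for (m in members[-1L]) {
          if (stats::runif(1) < noise$p_merge) {
            out[[length(out)]] <- rbind(out[[length(out)]], m)
          } else out <- c(out, list(m))
        }
        members <- out
      }
      if (noise$p_decorate > 0) {
        members <- lapply(members, function(m) {
          dec <- stats::runif(nrow(m)) < noise$p_decorate
          m$id[dec] <- .decorate_id(m$id[dec], m$species[dec])
          m
        })
      }
      groups <- lapply(seq_along(members), function(j) {
        ortho_group(tool, sprintf("G%04d", j), members[[j]])
      })
      tool_output(tool, sp, groups, provenance = list(synthetic = TRUE))
    })
  })
  names(tool_outputs) <- .tool_tags
  list(tool_outputs = tool_outputs,
       gtf = stats::setNames(lapply(sp, function(s) render_gtf(truth, s)), sp),
       gpff = stats::setNames(lapply(sp, function(s) render_gpff(truth, s)), sp))
}

#' Render synthetic GTF / GPFF fragments for one species of a ground truth
#'
#' The fragments carry exactly the protein-to-gene keys of the truth's
#' protein table, in the form the idmap builders consume: GTF CDS lines with
#' `protein_id` and `db_xref "GeneID:<n>"` attributes, and minimal GPFF
#' records with `VERSION` and a CDS `/db_xref="GeneID:<n>"` qualifier.
#'
#' @param truth A `ground_truth`.
#' @param species One species tag of the pair.
#' @return Character vector of lines.
#' @export
render_gtf <- function(truth, species) {
  pt <- truth$protein_table[truth$protein_table$species == species, , drop = FALSE]
  if (!nrow(pt)) return(character())
  sprintf(paste0("scf1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\t",
                 "gene_id \"LOC%d\"; db_xref \"GeneID:%d\"; protein_id \"%s\";"),
          100L * seq_len(nrow(pt)), 100L * seq_len(nrow(pt)) + 50L,
          pt$gene, pt$gene, pt$accession)
}

#' @rdname render_gtf
#' @export
render_gpff <- function(truth, species) {
  pt <- truth$protein_table[truth$protein_table$species == species, , drop = FALSE]
  unlist(lapply(seq_len(nrow(pt)), function(i) {
    c(sprintf("LOCUS       %s  100 aa  linear  INV", .strip_version(pt$accession[i])),
      sprintf("VERSION     %s", pt$accession[i]),
      "FEATURES             Location/Qualifiers",
      "     CDS             1..100",
      sprintf("                     /db_xref=\"GeneID:%d\"", pt$gene[i]),
      "//")
  }))
}

#' Write a full fixture directory
#'
#' Renders a ground truth (with noise) and writes one native output file per
#' tool, `gtf/<species>.gtf`, `gpff/<species>.gpff` and `truth.tsv`
#' (the planted relations, one member per row).
#'
#' @inheritParams render_tool_outputs
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture_dir <- function(truth, dir, noise = noise_model(),
                              master_seed = truth$seed) {
  rendered <- render_tool_outputs(truth, noise, master_seed)
  dir.create(file.path(dir, "gtf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gpff"), recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (tool in .tool_tags) {
    p <- file.path(dir, paste0(tool, ".txt"))
    write_tool_output(tool, rendered$tool_outputs[[tool]], p)
    paths[[tool]] <- p
  }
  for (s in truth$species_pair) {
    writeLines(rendered$gtf[[s]], file.path(dir, "gtf", paste0(s, ".gtf")))
    writeLines(rendered$gpff[[s]], file.path(dir, "gpff", paste0(s, ".gpff")))
  }
  rel <- do.call(rbind, lapply(seq_along(truth$relations), function(i) {
    r <- truth$relations[[i]]
    data.frame(relation = i, category = r$category,
               species = c(rep(truth$species_pair[1L], length(r$genes_a)),
                           rep(truth$species_pair[2L], length(r$genes_b))),
               gene = c(r$genes_a, r$genes_b), stringsAsFactors = FALSE)
  }))
  tl <- c("relation\tcategory\tspecies\tgene",
          if (!is.null(rel)) paste(rel$relation, rel$category, rel$species, rel$gene, sep = "\t"))
  writeLines(tl, file.path(dir, "truth.tsv"))
  paths$truth <- file.path(dir, "truth.tsv")
  invisible(paths)
}

#' Score recovered consensus calls against a planted truth
#'
#' Standard set precision/recall/F1 of the called gene pairs against the
#' truth's one2one pairs. With no calls precision is undefined (`NaN`,
#' flagged via `n_called = 0`) and recall is 0.
#'
#' @param calls A `consensus_calls` (or data frame with `gene_a`, `gene_b`).
#' @param truth A `ground_truth` for the same species pair.
#' @return List: `precision`, `recall`, `f1`, `n_called`, `n_true`, `n_tp`.
#' @export
score_recovery <- function(calls, truth) {
  truth_pairs <- truth_one2one_pairs(truth)
  called <- unique(paste(calls$gene_a, calls$gene_b))
  true <- paste(truth_pairs$gene_a, truth_pairs$gene_b)
  tp <- sum(called %in% true)
  precision <- if (length(called)) tp / length(called) else NaN
  recall <- if (length(true)) tp / length(true) else NaN
  f1 <- if (!is.nan(precision) && !is.nan(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NaN
  list(precision = precision, recall = recall, f1 = f1,
       n_called = length(called), n_true = length(true), n_tp = tp)
}
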