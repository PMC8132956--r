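#' Filter orthogroups containing only one species
#'
#' Orthology tools also report within-species paralog clusters; a group whose
#' members all come from one species cannot witness orthology and is removed.
#'
#' @param groups List of [ortho_group()] objects.
#' @return List with `kept` (groups with >= 2 distinct species, order
#'   preserved) and `n_removed`.
#' @export
filter_single_species <- function(groups) {
  multi <- vapply(groups, function(g) length(unique(g$members$species)) >= 2L,
                  logical(1))
  list(kept = groups[multi], n_removed = sum(!multi))
}

#' Strip a member token to its bare RefSeq accession
#'
#' Tool outputs decorate protein identifiers (`"sp|XP_1.1|NAME"`,
#' `"XP_1.1_Species"`, ...). The first substring matching the RefSeq protein
#' accession pattern (two letters, underscore, digits, optional version) is
#' returned; tokens with no such substring yield `NA`.
#'
#' @param token Character vector of raw member tokens.
#' @return Character vector of accessions, `NA` where unparseable.
#' @export
strip_to_refseq <- function(token) {
  # the two accession letters must start a word: "scaffold_441" is not "ld_441"
  m <- regexpr(paste0("(?<![A-Za-z])", .refseq_re), token, perl = TRUE)
  out <- rep(NA_character_, length(token))
  hit <- m != -1L
  out[hit] <- regmatches(token, m)
  out
}

.gene_members_df <- function(species = character(), gene = integer()) {
  data.frame(species = species, gene = as.integer(gene), stringsAsFactors = FALSE)
}

.gene_group <- function(tool, group_id, members) {
  members <- unique(members)
  rownames(members) <- NULL
  structure(list(tool = tool, group_id = as.character(group_id),
                 members = members,
                 flags = .group_flags(members), level = "gene"),
            class = c("gene_ortho_group"))
}

.group_flags <- function(members, species_pair = NULL) {
  per_sp <- table(members$species)
  one_each <- all(per_sp == 1L)
  both <- if (is.null(species_pair)) length(per_sp) >= 2L else
    all(species_pair %in% names(per_sp))
  list(is_candidate_1to1 = one_each && both,
       has_coorthologs = any(per_sp >= 2L))
}

#' Collapse gene-level groups sharing any member
#'
#' After protein-to-gene mapping, one gene can surface in several groups of
#' the same tool output. Groups connected by any shared `(species, gene)`
#' member are merged (union of members, transitively), so that each gene
#' occurs in at most one group per output. The merged group takes the
#' lexicographically smallest constituent id.
#'
#' @param groups List of gene-level groups (as produced by [to_gene_level()]).
#' @return List of merged groups, with attribute `n_merged` counting merge
#'   events (number of groups absorbed into another).
#' @export
collapse_duplicates <- function(groups) {
  n <- length(groups)
  if (n == 0L) return(structure(list(), n_merged = 0L))
  # union-find over group indices, keyed by (species, gene) membership
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  seen <- new.env(parent = emptyenv(), size = 4L * n)
  for (i in seq_len(n)) {
    keys <- paste(groups[[i]]$members$species, groups[[i]]$members$gene)
    for (k in keys) {
      j <- get0(k, envir = seen)
      if (is.null(j)) assign(k, i, envir = seen)
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    members <- unique(do.call(rbind, lapply(groups[idx], `[[`, "members")))
    ids <- vapply(groups[idx], `[[`, character(1), "group_id")
    .gene_group(groups[[idx[1L]]]$tool, min(ids), members)
  })
  structure(out, n_merged = n - length(out))
}

#' Normalize a protein-level tool output to gene-level orthogroups
#'
#' Applies the full normalization cascade to one tool's parsed output:
#' single-species groups are removed; each member token is stripped to its
#' RefSeq accession and mapped to an Entrez gene ID; members of one group
#' mapping to the same gene deduplicate silently (many RefSeq proteins per
#' gene); unmappable members are dropped and counted (or abort in strict
#' mode); groups left with one species after the losses are removed again
#' (when `refilter` is on); finally [collapse_duplicates()] enforces that
#' each gene occurs in at most one group, and candidate-1:1 / co-ortholog
#' flags are computed.
#'
#' @param output A protein-level [tool_output()].
#' @param idmaps Named list of [idmap()]s, one per species of the pair.
#' @param strict Abort on the first unmappable member instead of dropping it.
#' @param refilter Re-apply the single-species filter after mapping losses
#'   (default `TRUE`).
#' @return A `normalized_output`: fields `tool`, `species_pair`, `groups`
#'   (gene-level groups with flags) and `audit` (counts `groups_in`,
#'   `single_species_filtered`, `ids_unmapped`, `groups_merged`,
#'   `groups_out`).
#' @export
to_gene_level <- function(output, idmaps, strict = FALSE, refilter = TRUE) {
  stopifnot(inherits(output, "tool_output"))
  sp <- output$species_pair
  missing_maps <- setdiff(sp, names(idmaps))
  if (length(missing_maps)) {
    .config_error("no idmap supplied for species: ", paste(missing_maps, collapse = ", "))
  }
  audit <- list(groups_in = length(output$groups), single_species_filtered = 0L,
                ids_unmapped = 0L, groups_merged = 0L, groups_out = 0L)

  fs <- filter_single_species(output$groups)
  audit$single_species_filtered <- fs$n_removed
  idx <- lapply(idmaps[sp], .idmap_index)

  gene_groups <- list()
  for (g in fs$kept) {
    acc <- strip_to_refseq(g$members$id)
    gene <- rep(NA_integer_, length(acc))
    for (s in unique(g$members$species)) {
      sel <- g$members$species == s & !is.na(acc)
      if (!any(sel)) next
      hit <- unname(idx[[s]]$exact[acc[sel]])
      miss <- is.na(hit)
      hit[miss] <- unname(idx[[s]]$versionless[.strip_version(acc[sel][miss])])
      gene[sel] <- hit
    }
    lost <- is.na(gene)
    if (any(lost)) {
      if (strict) {
        .data_error("unmappable member '", g$members$id[lost][1L],
                    "' in ", output$tool, " group ", g$group_id)
      }
      audit$ids_unmapped <- audit$ids_unmapped + sum(lost)
    }
    members <- .gene_members_df(g$members$species[!lost], gene[!lost])
    members <- unique(members)   # silent many-proteins -> one-gene dedup
    if (nrow(members) == 0L) next
    gene_groups[[length(gene_groups) + 1L]] <-
      .gene_group(output$tool, g$group_id, members)
  }

  if (refilter) {
    fs2 <- filter_single_species(gene_groups)
    audit$single_species_filtered <- audit$single_species_filtered + fs2$n_removed
    gene_groups <- fs2$kept
  }

  gene_groups <- collapse_duplicates(gene_groups)
  audit$groups_merged <- attr(gene_groups, "n_merged")
  # flags must see the full species pair, not just the species present
  gene_groups <- lapply(gene_groups, function(g) {
    g$flags <- .group_flags(g$members, species_pair = sp)
    g
  })
  audit$groups_out <- length(gene_groups)
  structure(list(tool = output$tool, species_pair = sp,
                 groups = gene_groups, audit = audit),
            class = "normalized_output")
}

#' @export
print.normalized_output <- function(x, ...) {
  a <- x$audit
  cat("<normalized_output>", x$tool, paste(x$species_pair, collapse = " vs "), "\n",
      " groups:", a$groups_in, "in ->", a$groups_out, "out",
      "(", a$single_species_filtered, "single-species filtered,",
      a$ids_unmapped, "ids unmapped,", a$groups_merged, "merged )\n")
  invisible(x)
}

#' Write a normalized output as TSV
#'
#' One row per gene-level member: `tool`, `group_id`, `species`,
#' `entrez_gene_id`, `is_candidate_1to1`, `has_coorthologs`, with header.
#'
#' @param x A `normalized_output`.
#' @param path Optional output path.
#' @return The lines, invisibly.
#' @export
write_normalized_tsv <- function(x, path = NULL) {
  stopifnot(inherits(x, "normalized_output"))
  rows <- unlist(lapply(x$groups, function(g) {
    paste(x$tool, g$group_id, g$members$species, g$members$gene,
          g$flags$is_candidate_1to1, g$flags$has_coorthologs, sep = "\t")
  }))
  .emit_lines(c("tool\tgroup_id\tspecies\tentrez_gene_id\tis_candidate_1to1\thas_coorthologs",
                rows), path)
}
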