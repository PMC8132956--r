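#' Protein-level orthogroups and tool outputs
#'
#' An `ortho_group` is one cluster reported by an orthology tool: a non-empty
#' set of `(species, identifier)` members at protein level (as parsed) or gene
#' level (after normalization). A `tool_output` bundles all groups parsed from
#' one tool's native output for one ordered species pair (anchor species
#' first), with parse provenance.
#'
#' @param tool Tool tag, one of `"orthofinder"`, `"proteinortho"`,
#'   `"inparanoid"`, `"oma"`, `"swiftortho"`, `"fastortho"`.
#' @param group_id Group label, unique within one tool output.
#' @param members Data frame with columns `species` and `id`.
#' @param level `"protein"` or `"gene"`.
#' @return An object of class `ortho_group`.
#' @export
ortho_group <- function(tool, group_id, members, level = "protein") {
  stopifnot(is.data.frame(members), all(c("species", "id") %in% names(members)))
  members <- unique(members[, c("species", "id"), drop = FALSE])
  rownames(members) <- NULL
  if (nrow(members) == 0L) stop("ortho_group members must be non-empty")
  structure(list(tool = tool, group_id = as.character(group_id),
                 members = members, level = level),
            class = "ortho_group")
}

#' @rdname ortho_group
#' @param species_pair Ordered pair of species tags (anchor first).
#' @param groups List of `ortho_group`.
#' @param provenance List of parse statistics (source, warnings, counts).
#' @export
tool_output <- function(tool, species_pair, groups, provenance = list()) {
  stopifnot(is.character(species_pair), length(species_pair) == 2L)
  ids <- vapply(groups, `[[`, character(1), "group_id")
  if (anyDuplicated(ids)) {
    .data_error("duplicate group_id in ", tool, " output: ",
                ids[duplicated(ids)][1L])
  }
  for (g in groups) {
    bad <- setdiff(unique(g$members$species), species_pair)
    if (length(bad)) {
      .data_error(tool, " group ", g$group_id, " names species outside the pair: ",
                  paste(bad, collapse = ", "))
    }
  }
  structure(list(tool = tool, species_pair = species_pair, groups = groups,
                 provenance = provenance),
            class = "tool_output")
}

#' @export
print.tool_output <- function(x, ...) {
  cat("<tool_output>", x$tool, paste(x$species_pair, collapse = " vs "),
      "-", length(x$groups), "groups\n")
  invisible(x)
}

# Resolve proteome labels (filenames, uppercase tags, ...) to species tags.
# Explicit species_labels (named vector label -> tag) take precedence; then an
# exact tag match, a filename with its extension stripped, and finally a
# case-insensitive tag match.
.resolve_species <- function(labels, species_pair, species_labels = NULL,
                             what = "proteome label") {
  out <- rep(NA_character_, length(labels))
  if (!is.null(species_labels)) out <- unname(species_labels[labels])
  try_fill <- function(out, cand) {
    miss <- is.na(out)
    out[miss] <- ifelse(cand[miss] %in% species_pair, cand[miss], NA_character_)
    out
  }
  out <- try_fill(out, labels)
  out <- try_fill(out, sub("\\.(faa|fa|fasta|pep)(\\.gz)?$", "", labels))
  miss <- is.na(out)
  hit <- match(toupper(labels[miss]), toupper(species_pair))
  out[miss] <- species_pair[hit]
  if (anyNA(out)) {
    .data_error("unknown ", what, ": ",
                paste(unique(labels[is.na(out)]), collapse = ", "),
                " (expected one of: ", paste(species_pair, collapse = ", "), ")")
  }
  out
}

.members_df <- function(species, id) {
  data.frame(species = species, id = id, stringsAsFactors = FALSE)
}

#' Read the six orthology-tool output dialects
#'
#' Each reader parses one tool's native cluster-level output into a
#' [tool_output()] of protein-level groups. Dialects:
#' * `read_orthofinder()`: Orthogroups TSV — header `Orthogroup` plus one
#'   column per species; cells are `", "`-separated protein IDs, empty cell =
#'   species absent.
#' * `read_proteinortho()`: header `# Species\tGenes\tAlg.-Conn.` plus one
#'   column per proteome file; cells comma-separated, `*` = absent.
#' * `read_inparanoid()`: sqltable — `cluster_id`, `bit_score`,
#'   `proteome_label`, `inparalog_score`, `protein_id` per line; lines sharing
#'   a cluster id form one group regardless of adjacency.
#' * `read_oma()`: orthologous-groups file — `#` comments, then one group per
#'   line: label followed by `SPECIES:protein_id` tokens.
#' * `read_swiftortho()`: one cluster per line of `species|protein_id` tokens.
#' * `read_fastortho()`: `.end` dialect —
#'   `NAME (N genes,M taxa):\t id(taxon) ...`; a member count disagreeing
#'   with `N` is a warning recorded in provenance, not an error.
#'
#' @param x Input: file path (gzip detected by suffix), connection, or
#'   character vector of lines.
#' @param species_pair Ordered pair of species tags (anchor first).
#' @param species_labels Optional named character vector mapping proteome
#'   labels used in the file to species tags (required when labels are not
#'   recognizable variants of the tags).
#' @return A [tool_output()] with `level = "protein"` groups.
#' @name read_tool
NULL

#' @rdname read_tool
#' @export
read_orthofinder <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  if (!length(lines)) .data_error("orthofinder output is empty (no header)")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L) {
    .data_error("orthofinder header: expected orthogroup column plus ",
                length(species_pair), " species columns, found ",
                length(hdr) - 1L, " (header: ", lines[1L], ")")
  }
  col_sp <- .resolve_species(hdr[-1L], species_pair, species_labels,
                             what = "orthofinder header column")
  if (!setequal(col_sp, species_pair)) {
    .data_error("orthofinder header species mismatch: expected ",
                paste(species_pair, collapse = ", "), "; found ",
                paste(col_sp, collapse = ", "))
  }
  groups <- list()
  for (ln in lines[-1L]) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    length(f) <- length(hdr)
    f[is.na(f)] <- ""
    sp <- character(); id <- character()
    for (j in 2L:length(hdr)) {
      if (!nzchar(trimws(f[j]))) next
      ids <- strsplit(trimws(f[j]), ",\\s*")[[1L]]
      sp <- c(sp, rep(col_sp[j - 1L], length(ids)))
      id <- c(id, ids)
    }
    if (!length(id)) next
    groups[[length(groups) + 1L]] <- ortho_group("orthofinder", f[1L], .members_df(sp, id))
  }
  tool_output("orthofinder", species_pair, groups,
              provenance = list(n_lines = length(lines)))
}

#' @rdname read_tool
#' @export
read_proteinortho <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  if (!length(lines) || !startsWith(lines[1L], "# Species\tGenes\tAlg.-Conn.")) {
    .data_error("proteinortho output must start with '# Species\\tGenes\\tAlg.-Conn.'")
  }
  hdr <- strsplit(sub("^# ", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  prot_cols <- hdr[-(1:3)]
  col_sp <- .resolve_species(prot_cols, species_pair, species_labels)
  groups <- list()
  n <- 0L
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(hdr)) {
      .data_error("proteinortho line ", i, ": ", length(f),
                  " columns, header has ", length(hdr))
    }
    n <- n + 1L
    sp <- character(); id <- character()
    for (j in seq_along(prot_cols)) {
      cell <- f[j + 3L]
      if (cell == "*" || !nzchar(cell)) next
      ids <- strsplit(cell, ",", fixed = TRUE)[[1L]]
      sp <- c(sp, rep(col_sp[j], length(ids)))
      id <- c(id, ids)
    }
    if (!length(id)) next
    groups[[length(groups) + 1L]] <-
      ortho_group("proteinortho", paste0("PO", n), .members_df(sp, id))
  }
  tool_output("proteinortho", species_pair, groups,
              provenance = list(n_lines = length(lines)))
}

#' @rdname read_tool
#' @export
read_inparanoid <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(tool_output("inparanoid", species_pair, list()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 5L)) {
    .data_error("inparanoid sqltable line ", which(lengths(f) != 5L)[1L],
                ": expected 5 tab-delimited fields")
  }
  cl <- vapply(f, `[[`, character(1), 1L)
  lab <- vapply(f, `[[`, character(1), 3L)
  pid <- vapply(f, `[[`, character(1), 5L)
  sp <- .resolve_species(lab, species_pair, species_labels)
  groups <- lapply(unique(cl), function(ci) {
    sel <- cl == ci
    ortho_group("inparanoid", paste0("IP", ci), .members_df(sp[sel], pid[sel]))
  })
  tool_output("inparanoid", species_pair, groups,
              provenance = list(n_lines = length(lines)))
}

#' @rdname read_tool
#' @export
read_oma <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  groups <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1L]]
    members <- tok[-1L]
    if (!all(grepl(":", members, fixed = TRUE))) {
      .data_error("oma line ", i, ": member token without ':' separator")
    }
    lab <- sub(":.*$", "", members)
    pid <- sub("^[^:]*:", "", members)
    sp <- .resolve_species(lab, species_pair, species_labels)
    groups[[length(groups) + 1L]] <- ortho_group("oma", tok[1L], .members_df(sp, pid))
  }
  tool_output("oma", species_pair, groups, provenance = list(n_lines = length(lines)))
}

#' @rdname read_tool
#' @export
read_swiftortho <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  groups <- list()
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    n <- n + 1L
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (!all(grepl("|", tok, fixed = TRUE))) {
      .data_error("swiftortho line ", i, ": member token without '|' separator")
    }
    lab <- sub("\\|.*$", "", tok)
    pid <- sub("^[^|]*\\|", "", tok)
    sp <- .resolve_species(lab, species_pair, species_labels)
    groups[[length(groups) + 1L]] <-
      ortho_group("swiftortho", paste0("SW", n), .members_df(sp, pid))
  }
  tool_output("swiftortho", species_pair, groups,
              provenance = list(n_lines = length(lines)))
}

#' @rdname read_tool
#' @export
read_fastortho <- function(x, species_pair, species_labels = NULL) {
  lines <- .as_lines(x)
  groups <- list()
  n_count_mismatch <- 0L
  re <- "^(\\S+)\\s+\\((\\d+) genes,(\\d+) taxa\\):\\s*(.*)$"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (!grepl(re, ln)) .data_error("fastortho line ", i, ": not in '.end' group format")
    gname <- sub(re, "\\1", ln)
    n_decl <- as.integer(sub(re, "\\2", ln))
    body <- sub(re, "\\4", ln)
    tok <- strsplit(trimws(body), "\\s+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (!all(grepl("\\(.+\\)$", tok))) {
      .data_error("fastortho line ", i, ": member token without '(taxon)' suffix")
    }
    pid <- sub("\\([^()]*\\)$", "", tok)
    lab <- sub("^.*\\(([^()]*)\\)$", "\\1", tok)
    sp <- .resolve_species(lab, species_pair, species_labels, what = "fastortho taxon")
    if (length(tok) != n_decl) {
      n_count_mismatch <- n_count_mismatch + 1L
      warning("fastortho group ", gname, ": declared ", n_decl, " genes, found ",
              length(tok), call. = FALSE)
    }
    groups[[length(groups) + 1L]] <- ortho_group("fastortho", gname, .members_df(sp, pid))
  }
  tool_output("fastortho", species_pair, groups,
              provenance = list(n_lines = length(lines),
                                n_count_mismatch = n_count_mismatch))
}

#' @rdname read_tool
#' @param tool Tool tag selecting the dialect.
#' @export
read_tool_output <- function(tool, x, species_pair, species_labels = NULL) {
  reader <- switch(tool,
    orthofinder = read_orthofinder, proteinortho = read_proteinortho,
    inparanoid = read_inparanoid, oma = read_oma,
    swiftortho = read_swiftortho, fastortho = read_fastortho,
    .config_error("unknown tool tag: ", tool))
  reader(x, species_pair, species_labels)
}

#' Write tool outputs back into their native dialects
#'
#' Inverse of the [read_tool] family, used by the synthetic-fixture renderer.
#' Re-reading a written file reproduces the member sets exactly (group ids may
#' be renumbered by dialects that carry no label).
#'
#' @param output A [tool_output()].
#' @param path Optional file path or connection; when `NULL` the rendered
#'   lines are returned invisibly.
#' @return The rendered lines, invisibly.
#' @name write_tool
NULL

.ids_for <- function(g, sp) g$members$id[g$members$species == sp]

#' @rdname write_tool
#' @export
write_orthofinder <- function(output, path = NULL) {
  sp <- output$species_pair
  rows <- vapply(output$groups, function(g) {
    paste(g$group_id,
          paste(.ids_for(g, sp[1L]), collapse = ", "),
          paste(.ids_for(g, sp[2L]), collapse = ", "), sep = "\t")
  }, character(1))
  .emit_lines(c(paste(c("Orthogroup", sp), collapse = "\t"), rows), path)
}

#' @rdname write_tool
#' @export
write_proteinortho <- function(output, path = NULL) {
  sp <- output$species_pair
  hdr <- paste(c("# Species", "Genes", "Alg.-Conn.", paste0(sp, ".faa")),
               collapse = "\t")
  rows <- vapply(output$groups, function(g) {
    a <- .ids_for(g, sp[1L]); b <- .ids_for(g, sp[2L])
    cell <- function(v) if (length(v)) paste(v, collapse = ",") else "*"
    paste(length(unique(g$members$species)), nrow(g$members), "1",
          cell(a), cell(b), sep = "\t")
  }, character(1))
  .emit_lines(c(hdr, rows), path)
}

#' @rdname write_tool
#' @export
write_inparanoid <- function(output, path = NULL) {
  lines <- character()
  for (i in seq_along(output$groups)) {
    g <- output$groups[[i]]
    lines <- c(lines, paste(i, "1000", paste0(g$members$species, ".faa"),
                            "1.000", g$members$id, sep = "\t"))
  }
  .emit_lines(lines, path)
}

#' @rdname write_tool
#' @export
write_oma <- function(output, path = NULL) {
  rows <- vapply(seq_along(output$groups), function(i) {
    g <- output$groups[[i]]
    paste(paste0("OMA", i),
          paste(toupper(g$members$species), g$members$id, sep = ":", collapse = " "))
  }, character(1))
  .emit_lines(c("# Orthologous groups", rows), path)
}

#' @rdname write_tool
#' @export
write_swiftortho <- function(output, path = NULL) {
  rows <- vapply(output$groups, function(g) {
    paste(g$members$species, g$members$id, sep = "|", collapse = " ")
  }, character(1))
  .emit_lines(rows, path)
}

#' @rdname write_tool
#' @export
write_fastortho <- function(output, path = NULL) {
  rows <- vapply(seq_along(output$groups), function(i) {
    g <- output$groups[[i]]
    paste0("ORTHOMCL", i, " (", nrow(g$members), " genes,",
           length(unique(g$members$species)), " taxa):\t ",
           paste0(g$members$id, "(", g$members$species, ")", collapse = " "))
  }, character(1))
  .emit_lines(rows, path)
}

#' @rdname write_tool
#' @param tool Tool tag selecting the dialect.
#' @export
write_tool_output <- function(tool, output, path = NULL) {
  writer <- switch(tool,
    orthofinder = write_orthofinder, proteinortho = write_proteinortho,
    inparanoid = write_inparanoid, oma = write_oma,
    swiftortho = write_swiftortho, fastortho = write_fastortho,
    .config_error("unknown tool tag: ", tool))
  writer(output, path)
}
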