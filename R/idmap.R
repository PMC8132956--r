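#' RefSeq-to-Entrez identifier maps
#'
#' An `idmap` holds, for one species, the mapping from RefSeq protein
#' accessions (e.g. `"XP_000000001.1"`) to Entrez gene IDs. Maps are built
#' from GTF annotation files ([build_idmap_from_gtf()]) and/or RefSeq GPFF
#' protein records ([build_idmap_from_gpff()]) and combined with
#' [merge_idmaps()]. Many protein accessions may map to one gene ID; a
#' versionless accession resolves to exactly one gene (highest version wins
#' when versions disagree).
#'
#' @param species Species tag (short label, e.g. `"Sp"`).
#' @param accession Character vector of versioned RefSeq protein accessions.
#' @param gene_id Integer vector of Entrez gene IDs (positive).
#' @param source Character vector naming the key source (`"gtf"`, `"gpff"`, ...).
#' @param audit Named list of parse/skip counts kept for logging.
#' @return An object of class `idmap` with fields `species`, `entries`
#'   (data frame: `accession`, `gene_id`, `source`) and `audit`.
#' @export
idmap <- function(species, accession = character(), gene_id = integer(),
                  source = character(), audit = .idmap_audit()) {
  stopifnot(is.character(species), length(species) == 1L)
  accession <- as.character(accession)
  gene_id <- as.integer(gene_id)
  if (length(source) == 1L) source <- rep(source, length(accession))
  if (length(accession) != length(gene_id)) {
    stop("accession and gene_id must have equal length")
  }
  bad <- !.is_refseq(accession)
  if (any(bad)) {
    stop("accession(s) not in RefSeq form: ", paste(utils::head(accession[bad], 3L), collapse = ", "))
  }
  if (any(!is.na(gene_id) & gene_id <= 0L)) stop("gene IDs must be positive integers")
  entries <- data.frame(accession = accession, gene_id = gene_id,
                        source = as.character(source), stringsAsFactors = FALSE)
  entries <- unique(entries)
  structure(list(species = species, entries = entries, audit = audit),
            class = "idmap")
}

#' @export
print.idmap <- function(x, ...) {
  cat("<idmap> species:", x$species, "-", nrow(x$entries), "protein accessions ->",
      length(unique(x$entries$gene_id)), "genes\n")
  sc <- source_counts(x)
  if (length(sc)) cat("  sources:", paste(names(sc), sc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-source entry tallies of an idmap
#' @param m An `idmap`.
#' @return Named integer vector of entry counts per key source.
#' @export
source_counts <- function(m) {
  stopifnot(inherits(m, "idmap"))
  tab <- table(m$entries$source)
  stats::setNames(as.integer(tab), names(tab))
}

# Exact + versionless lookup indices. Versionless: highest accession version
# wins; remaining ties resolved toward the smaller gene ID for determinism.
.idmap_index <- function(m) {
  e <- m$entries
  exact <- stats::setNames(e$gene_id, e$accession)
  exact <- exact[!duplicated(names(exact))]
  base <- .strip_version(e$accession)
  ver <- .accession_version(e$accession)
  ver[is.na(ver)] <- -1L
  ord <- order(base, -ver, e$gene_id)
  b <- base[ord]
  keep <- !duplicated(b)
  versionless <- stats::setNames(e$gene_id[ord][keep], b[keep])
  list(exact = exact, versionless = versionless)
}

#' Look up the Entrez gene ID(s) for protein accessions
#'
#' Exact versioned matches are preferred; otherwise the versionless accession
#' is resolved (highest stored version wins). Not-found is returned as `NA`,
#' never raised as an error.
#'
#' @param m An `idmap`.
#' @param protein_id Character vector of protein accessions (versioned or not).
#' @return Integer vector of gene IDs, `NA` where not found.
#' @export
lookup_gene <- function(m, protein_id) {
  stopifnot(inherits(m, "idmap"))
  idx <- .idmap_index(m)
  out <- unname(idx$exact[protein_id])
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- unname(idx$versionless[.strip_version(protein_id[miss])])
  }
  as.integer(out)
}

#' Build an idmap from GTF annotation text
#'
#' Scans attribute column 9 of each feature line for a `protein_id` and an
#' Entrez gene identifier, taken from a `db_xref "GeneID:<n>"` attribute or,
#' failing that, an all-numeric `gene_id`. Attribute extraction is key-based
#' (one regex per attribute), so attribute order never matters. Lines carrying
#' a `protein_id` but no resolvable gene ID are skipped and counted.
#'
#' @param x GTF text: a file path (gzip detected), connection, or character
#'   vector of lines.
#' @param species Species tag.
#' @return An `idmap`; `$audit` reports `n_skipped_no_gene`,
#'   `n_skipped_bad_accession` and `n_conflicts`.
#' @export
build_idmap_from_gtf <- function(x, species) {
  lines <- .as_lines(x)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(idmap(species, audit = .idmap_audit()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    .data_error("malformed GTF line ", lnum[bad], ": expected 9 tab-delimited columns, found ", nf[bad])
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  pid <- .gtf_attr(attrs, "protein_id")
  gid <- .gtf_geneid(attrs)
  has_pid <- !is.na(pid)
  pid <- pid[has_pid]
  gid <- gid[has_pid]
  no_gene <- is.na(gid)
  bad_acc <- !no_gene & !.is_refseq(pid)
  ok <- !no_gene & !bad_acc
  m <- idmap(species, pid[ok], gid[ok], source = "gtf",
             audit = .idmap_audit(n_skipped_no_gene = sum(no_gene),
                                  n_skipped_bad_accession = sum(bad_acc)))
  .dedupe_idmap(m)
}

.idmap_audit <- function(n_skipped_no_gene = 0L, n_skipped_bad_accession = 0L,
                         n_conflicts = 0L) {
  list(n_skipped_no_gene = as.integer(n_skipped_no_gene),
       n_skipped_bad_accession = as.integer(n_skipped_bad_accession),
       n_conflicts = as.integer(n_conflicts))
}

.gtf_attr <- function(attrs, key) {
  re <- paste0("(?:^|;)\\s*", key, "\\s+\"([^\"]*)\"")
  m <- regexpr(re, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  out[hit] <- sub(re, "\\1", regmatches(attrs, m), perl = TRUE)
  out
}

.gtf_geneid <- function(attrs) {
  xref <- .gtf_attr(attrs, "db_xref")
  out <- rep(NA_integer_, length(attrs))
  gene <- grepl("^GeneID:[0-9]+$", xref)
  out[gene] <- as.integer(sub("^GeneID:", "", xref[gene]))
  # fall back to a purely numeric gene_id attribute
  miss <- is.na(out)
  if (any(miss)) {
    gid <- .gtf_attr(attrs[miss], "gene_id")
    num <- !is.na(gid) & grepl("^[0-9]+$", gid)
    out[miss][num] <- as.integer(gid[num])
  }
  out
}

# Same versioned accession claiming two gene IDs within one build: keep the
# first occurrence, count a conflict.
.dedupe_idmap <- function(m) {
  dup <- duplicated(m$entries$accession)
  m$audit$n_conflicts <- m$audit$n_conflicts + sum(dup)
  m$entries <- m$entries[!dup, , drop = FALSE]
  rownames(m$entries) <- NULL
  m
}

#' Build an idmap from RefSeq GPFF (GenBank protein flat file) records
#'
#' Each record contributes one entry keyed on its `VERSION` accession with the
#' gene ID taken from a CDS `/db_xref="GeneID:<n>"` qualifier. Records missing
#' the GeneID are skipped and counted; a `VERSION` accession that is not a
#' RefSeq protein accession is skipped and counted.
#'
#' @inheritParams build_idmap_from_gtf
#' @return An `idmap`.
#' @export
build_idmap_from_gpff <- function(x, species) {
  lines <- .as_lines(x)
  ends <- which(trimws(lines) == "//")
  tail_start <- if (length(ends)) ends[length(ends)] + 1L else 1L
  if (tail_start <= length(lines) && any(nzchar(trimws(lines[tail_start:length(lines)])))) {
    .data_error("truncated GPFF record: content after line ", tail_start - 1L,
                " has no terminating '//'")
  }
  audit <- .idmap_audit()
  acc <- character()
  gid <- integer()
  start <- 1L
  for (e in ends) {
    rec <- lines[start:(e - 1L)]
    start <- e + 1L
    vline <- grep("^VERSION", rec, value = TRUE)
    a <- if (length(vline)) strsplit(trimws(sub("^VERSION", "", vline[1L])), "\\s+")[[1L]][1L] else NA_character_
    g <- regmatches(rec, regexpr("/db_xref=\"GeneID:[0-9]+\"", rec))
    g <- if (length(unlist(g))) as.integer(sub(".*GeneID:([0-9]+).*", "\\1", unlist(g)[1L])) else NA_integer_
    if (is.na(a) || !.is_refseq(a)) {
      audit$n_skipped_bad_accession <- audit$n_skipped_bad_accession + 1L
    } else if (is.na(g)) {
      audit$n_skipped_no_gene <- audit$n_skipped_no_gene + 1L
    } else {
      acc <- c(acc, a)
      gid <- c(gid, g)
    }
  }
  .dedupe_idmap(idmap(species, acc, gid, source = "gpff", audit = audit))
}

#' Merge two idmaps for the same species
#'
#' Union of entries. When the same versioned accession maps to different gene
#' IDs, the entry whose source matches `precedence` wins (GPFF by default, the
#' protein-authoritative RefSeq source); same-source ties keep the smaller
#' gene ID. All conflicts are counted in the audit.
#'
#' @param a,b `idmap` objects with identical `species`.
#' @param precedence Source winning on conflict, `"gpff"` or `"gtf"`.
#' @return Merged `idmap`.
#' @export
merge_idmaps <- function(a, b, precedence = c("gpff", "gtf")) {
  stopifnot(inherits(a, "idmap"), inherits(b, "idmap"))
  precedence <- match.arg(precedence)
  if (!identical(a$species, b$species)) {
    .data_error("species mismatch in merge_idmaps: '", a$species, "' vs '", b$species, "'")
  }
  e <- unique(rbind(a$entries, b$entries))
  # a conflict is the same versioned accession claiming two different genes;
  # agreeing entries from both sources dedupe silently (preferred source kept)
  n_conf <- sum(!duplicated(e[, c("accession", "gene_id")]) & duplicated(e$accession))
  # order-independent conflict resolution: preferred source first, then gene ID
  pref <- ifelse(e$source == precedence, 0L, 1L)
  ord <- order(e$accession, pref, e$gene_id)
  e <- e[ord, , drop = FALSE]
  e <- e[!duplicated(e$accession), , drop = FALSE]
  audit <- .idmap_audit(
    n_skipped_no_gene = a$audit$n_skipped_no_gene + b$audit$n_skipped_no_gene,
    n_skipped_bad_accession = a$audit$n_skipped_bad_accession + b$audit$n_skipped_bad_accession,
    n_conflicts = a$audit$n_conflicts + b$audit$n_conflicts + n_conf)
  m <- idmap(a$species, e$accession, e$gene_id, e$source, audit = audit)
  if (n_conf > 0L) {
    warning(n_conf, " accession(s) with conflicting gene IDs resolved by ",
            precedence, " precedence", call. = FALSE)
  }
  m
}

#' Write / read the 3-column idmap TSV
#'
#' Columns `species_tag`, `protein_accession`, `entrez_gene_id` with a header
#' line. Reading back yields a map with the same species and accession-to-gene
#' entries (key sources are not serialized).
#'
#' @param m An `idmap`.
#' @param path Output/input file path (or `NULL` to return lines).
#' @return `write_idmap()` the lines, invisibly; `read_idmap()` an `idmap`.
#' @export
write_idmap <- function(m, path = NULL) {
  stopifnot(inherits(m, "idmap"))
  e <- m$entries[order(m$entries$accession), , drop = FALSE]
  lines <- c("species_tag\tprotein_accession\tentrez_gene_id",
             if (nrow(e)) paste(m$species, e$accession, e$gene_id, sep = "\t"))
  .emit_lines(lines, path)
}

#' @rdname write_idmap
#' @param x Input path, connection or lines (see [build_idmap_from_gtf()]).
#' @export
read_idmap <- function(x) {
  lines <- .as_lines(x)
  if (!length(lines) || lines[1L] != "species_tag\tprotein_accession\tentrez_gene_id") {
    .data_error("idmap TSV must start with its 3-column header")
  }
  lines <- lines[-1L][nzchar(lines[-1L])]
  if (!length(lines)) .data_error("idmap TSV has no data rows to name a species")
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3L)) .data_error("idmap TSV row with wrong column count")
  sp <- unique(vapply(f, `[[`, character(1), 1L))
  if (length(sp) != 1L) .data_error("idmap TSV mixes species tags: ", paste(sp, collapse = ", "))
  idmap(sp, vapply(f, `[[`, character(1), 2L),
        as.integer(vapply(f, `[[`, character(1), 3L)), source = "tsv")
}
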