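# Reading and writing the formats the pipeline touches, and assembling
# labeled per-virus gene tables.
#
# A "gene table" is the package's central container: a tibble with one row
# per coding sequence and columns
#   gene_id  - identifier, unique within a virus
#   virus_id - identifier of the virus the gene belongs to
#   seq      - CDS nucleotide string (DNA alphabet, coding strand, 5'->3')
#   label    - "early", "late" or "unlabeled"

.TEMPORAL_LABELS <- c("early", "late")

#' Construct a gene table
#'
#' Low-level constructor for the package's central container: a tibble
#' with one coding sequence per row (`gene_id`, `virus_id`, `seq`,
#' `label`). Most users build gene tables with [read_cds_fasta()] or
#' [read_genbank_cds()] instead.
#'
#' @param gene_id,virus_id Character identifiers (recycled as usual).
#' @param seq CDS nucleotide strings (uppercased on construction).
#' @param label Temporal labels (`"early"`, `"late"` or `"unlabeled"`).
#' @return A tibble with columns `gene_id`, `virus_id`, `seq`, `label`.
#' @export
new_gene_table <- function(gene_id, virus_id, seq, label = "unlabeled") {
  tibble::tibble(
    gene_id = as.character(gene_id),
    virus_id = as.character(virus_id),
    seq = toupper(as.character(seq)),
    label = as.character(label)
  )
}

# uppercase, RNA -> DNA; other symbols left for the ambiguity policy downstream
sanitize_seq <- function(seq) {
  gsub("U", "T", toupper(seq), fixed = TRUE)
}

# enforce the multiple-of-3 policy; returns the (possibly reduced) table
apply_frame_policy <- function(genes, frame_policy = c("drop", "trim")) {
  frame_policy <- match.arg(frame_policy)
  bad <- nchar(genes$seq) %% 3L != 0L
  if (any(bad)) {
    if (frame_policy == "drop") {
      warn(sprintf(
        "%d sequence(s) with length not a multiple of 3 dropped: %s",
        sum(bad), paste(head(genes$gene_id[bad], 5), collapse = ", ")
      ))
      genes <- genes[!bad, ]
    } else {
      warn(sprintf(
        "%d sequence(s) with length not a multiple of 3 trimmed to frame",
        sum(bad)
      ))
      genes$seq[bad] <- substr(genes$seq[bad], 1L,
                               nchar(genes$seq[bad]) %/% 3L * 3L)
    }
  }
  empty <- nchar(genes$seq) == 0L
  if (any(empty)) {
    warn(sprintf("%d empty sequence(s) dropped", sum(empty)))
    genes <- genes[!empty, ]
  }
  genes
}

warn_internal_stops <- function(genes) {
  if (nrow(genes) == 0) return(invisible(genes))
  has_internal_stop <- vapply(genes$seq, function(s) {
    cods <- split_codons(s)
    if (length(cods) > 1) cods <- cods[-length(cods)]
    any(cods %in% .STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
  if (any(has_internal_stop)) {
    warn(sprintf(
      "%d sequence(s) contain internal stop codons (kept): %s",
      sum(has_internal_stop),
      paste(head(genes$gene_id[has_internal_stop], 5), collapse = ", ")
    ))
  }
  invisible(genes)
}

#' Read coding sequences from a nucleotide FASTA file
#'
#' Each record becomes one row of a gene table. The header token before the
#' first whitespace is the `gene_id`. Sequences are uppercased and `U` is
#' mapped to `T`; any other non-ACGT symbol is retained and the codons
#' containing it are excluded from downstream codon-level counts.
#'
#' @param path Path to a FASTA file of CDS nucleotide sequences.
#' @param virus_id Virus identifier attached to every record.
#' @param frame_policy What to do with records whose length is not a
#'   multiple of 3: `"drop"` (default) removes them with a warning,
#'   `"trim"` truncates to the last complete codon.
#' @return A gene table (tibble) with columns `gene_id`, `virus_id`,
#'   `seq`, `label` (all `"unlabeled"`).
#' @export
read_cds_fasta <- function(path, virus_id = "virus", frame_policy = c("drop", "trim")) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(recs))
  genes <- new_gene_table(ids, virus_id, sanitize_seq(as.character(recs)))
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene_id in FASTA headers")
  }
  genes <- apply_frame_policy(genes, frame_policy)
  warn_internal_stops(genes)
  genes
}

#' Write a gene table to FASTA and (optionally) a label table
#'
#' @param genes A gene table.
#' @param path Output FASTA path.
#' @param label_path Optional path for a CSV label table
#'   (`virus_id,gene_id,label`; unlabeled genes are omitted).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path, label_path = NULL) {
  x <- Biostrings::BStringSet(genes$seq)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  if (!is.null(label_path)) {
    lab <- genes[genes$label %in% .TEMPORAL_LABELS,
                 c("virus_id", "gene_id", "label")]
    utils::write.csv(lab, label_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a temporal label table
#'
#' A comma- or tab-separated file with header `virus_id,gene_id,label`
#' where label is `early` or `late`.
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `virus_id`, `gene_id`, `label`.
#' @export
read_label_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  req <- c("virus_id", "gene_id", "label")
  if (!all(req %in% names(tab))) {
    abort("label table must have columns virus_id, gene_id, label")
  }
  tab <- tibble::as_tibble(tab[req])
  validate_label_table(tab)
  tab
}

validate_label_table <- function(table) {
  bad <- !table$label %in% .TEMPORAL_LABELS
  if (any(bad)) {
    abort(sprintf("labels must be 'early' or 'late'; found: %s",
                  paste(unique(table$label[bad]), collapse = ", ")))
  }
  dup <- duplicated(table[c("virus_id", "gene_id")])
  if (any(dup)) {
    conflicts <- table |>
      dplyr::group_by(.data$virus_id, .data$gene_id) |>
      dplyr::summarise(k = dplyr::n_distinct(.data$label), .groups = "drop")
    if (any(conflicts$k > 1)) {
      abort("conflicting labels for the same (virus_id, gene_id)")
    }
    abort("duplicate (virus_id, gene_id) rows in label table")
  }
  invisible(table)
}

#' Attach temporal labels to a gene table
#'
#' Genes matched by `(virus_id, gene_id)` in the label table get their
#' label; unmatched genes stay `"unlabeled"` and are excluded from
#' temporal analyses. Table rows that reference a missing gene produce a
#' warning, not an error.
#'
#' @param genes A gene table.
#' @param table A label table (see [read_label_table()]).
#' @return The gene table with its `label` column filled in.
#' @export
attach_labels <- function(genes, table) {
  validate_label_table(table)
  key_g <- paste(genes$virus_id, genes$gene_id, sep = "\r")
  key_t <- paste(table$virus_id, table$gene_id, sep = "\r")
  hit <- match(key_g, key_t)
  genes$label <- ifelse(is.na(hit), "unlabeled", table$label[hit])
  missed <- !(key_t %in% key_g)
  if (any(missed)) {
    warn(sprintf("%d label row(s) reference genes not present: %s",
                 sum(missed), paste(head(table$gene_id[missed], 5), collapse = ", ")))
  }
  inform(sprintf("labels attached: %d early, %d late, %d unlabeled",
                 sum(genes$label == "early"), sum(genes$label == "late"),
                 sum(genes$label == "unlabeled")))
  genes
}

#' Count temporal labels in a gene table
#'
#' @param genes A gene table.
#' @return A named integer vector with elements `early`, `late`, `unlabeled`.
#' @export
label_counts <- function(genes) {
  vapply(c(.TEMPORAL_LABELS, "unlabeled"),
         function(l) sum(genes$label == l), integer(1))
}

# require at least `min_per_group` genes per temporal group
check_temporal_groups <- function(genes, min_per_group = 2L) {
  n <- label_counts(genes)
  if (n[["early"]] < min_per_group || n[["late"]] < min_per_group) {
    abort(sprintf(
      "temporal analysis needs >= %d genes per group; found %d early, %d late",
      min_per_group, n[["early"]], n[["late"]]
    ))
  }
  invisible(n)
}

#' Extract coding sequences from a GenBank flat file
#'
#' Parses CDS features from a local GenBank record, honoring
#' `complement()` and `join()` location operators (1-based inclusive
#' coordinates). The `gene_id` comes from `locus_tag`, falling back to
#' `gene` and then `protein_id`. CDS with fuzzy boundaries (`<`/`>`) are
#' skipped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param virus_id Virus identifier; defaults to the LOCUS name.
#' @param frame_policy See [read_cds_fasta()].
#' @return A gene table.
#' @export
read_genbank_cds <- function(path, virus_id = NULL, frame_policy = c("drop", "trim")) {
  lines <- readLines(path)
  if (is.null(virus_id)) {
    locus <- grep("^LOCUS", lines, value = TRUE)
    virus_id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "virus"
  }
  ori_start <- grep("^ORIGIN", lines)
  if (length(ori_start) == 0) abort("GenBank record has no ORIGIN sequence block")
  seq_lines <- lines[(ori_start[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- gsub("U", "T", genome, fixed = TRUE)

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) abort("GenBank record has no FEATURES block")
  feat <- lines[(feat_start[1] + 1):(ori_start[1] - 1)]

  # group feature block lines: a new feature starts at column 6
  is_key <- grepl("^ {5}\\S", feat)
  idx <- cumsum(is_key)
  blocks <- split(feat, idx)
  cds_blocks <- Filter(function(b) grepl("^ {5}CDS\\s", b[1]), blocks)

  out <- list()
  skipped <- 0L
  for (b in cds_blocks) {
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", b)
    loc_lines <- if (length(qual_at)) b[seq_len(qual_at[1] - 1)] else b
    loc <- gsub("\\s", "", paste(sub("^ {5}CDS", "", loc_lines), collapse = ""))
    if (grepl("[<>]", loc)) {
      skipped <- skipped + 1L
      next
    }
    seq <- extract_location(genome, loc)
    qual <- paste(b[qual_at], collapse = "\n")
    id <- genbank_qualifier(qual, "locus_tag")
    if (is.na(id)) id <- genbank_qualifier(qual, "gene")
    if (is.na(id)) id <- genbank_qualifier(qual, "protein_id")
    if (is.na(id)) id <- sprintf("CDS_%s", loc)
    out[[length(out) + 1L]] <- list(gene_id = id, seq = seq)
  }
  if (skipped > 0) {
    warn(sprintf("%d CDS with fuzzy boundaries skipped", skipped))
  }
  if (length(out) == 0) abort("no usable CDS features found")
  ids <- vapply(out, `[[`, character(1), "gene_id")
  ids <- make.unique(ids, sep = "_")
  genes <- new_gene_table(ids, virus_id, vapply(out, `[[`, character(1), "seq"))
  genes <- apply_frame_policy(genes, frame_policy)
  warn_internal_stops(genes)
  genes
}

genbank_qualifier <- function(qual_text, name) {
  m <- regmatches(qual_text,
                  regexpr(sprintf('/%s="[^"]*"', name), qual_text))
  if (length(m) == 0) return(NA_character_)
  sub(sprintf('/%s="([^"]*)"', name), "\\1", m[1])
}

# resolve a GenBank location string (complement/join/ranges) to a sequence
extract_location <- function(genome, loc) {
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(revcomp(extract_location(genome, inner)))
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    return(paste(vapply(parts, function(p) extract_location(genome, p),
                        character(1)), collapse = ""))
  }
  if (grepl("^\\d+\\.\\.\\d+$", loc)) {
    bounds <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    if (bounds[2] > nchar(genome)) abort("CDS location beyond sequence end")
    return(substr(genome, bounds[1], bounds[2]))
  }
  if (grepl("^\\d+$", loc)) {
    return(substr(genome, as.integer(loc), as.integer(loc)))
  }
  abort(sprintf("unsupported GenBank location: %s", loc))
}
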