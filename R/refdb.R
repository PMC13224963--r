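#' Parse an annotated reference genome into a flank-extended gene database
#'
#' Reads a GenBank flat file (possibly multi-record, i.e. multi-contig) and
#' extracts one record per annotated gene. Because read mapping tapers off at
#' sequence ends, each gene is extended on both sides by a flank equal to the
#' sequencing read length (or less when the gene sits near a contig end); the
#' flank-extended sequence is what reads are mapped against, while variant
#' calling later restricts itself to the core gene positions.
#'
#' CDS features are preferred; if a record annotates no CDS at all, plain
#' `gene` features are used instead. Pseudo-genes (features carrying a
#' `/pseudo` qualifier) and features with compound (`join`/`order`)
#' locations are skipped. Genes are always stored in contig (plus-strand)
#' orientation so that mapping, pileup and genotype coordinates share a
#' single frame; the annotated strand is recorded but not used to
#' reverse-complement.
#'
#' @param path Path to a GenBank flat file (`.gb`/`.gbff`).
#' @param read_length Sequencing read length in bp used to size the flanks
#'   (default 150).
#' @return A `gene_db` data.frame with one row per gene and columns
#'   `gene_id`, `contig_id`, `gene_start`, `gene_end`, `strand`,
#'   `flank_left`, `flank_right`, `core_len` and `ext_seq` (the
#'   flank-extended sequence).
#' @export
#' @examples
#' gb <- tempfile(fileext = ".gb")
#' sim <- sim_design(n_genes = 3, gene_length = 300, n_strains = 1,
#'                   frequencies = 1, coverage = 5)
#' ref <- sim_reference(sim, seed = 1)
#' write_genbank(ref$contig, ref$genes, gb)
#' db <- read_genbank_genes(gb)
#' db$gene_id
read_genbank_genes <- function(path, read_length = 150) {
  if (!file.exists(path)) {
    stop("GenBank file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    stop("not a parsable GenBank flat file: ", path)
  }
  rec_breaks <- c(0L, which(trimws(lines) == "//"))
  recs <- list()
  for (i in seq_len(length(rec_breaks) - 1L)) {
    block <- lines[(rec_breaks[i] + 1L):(rec_breaks[i + 1L] - 1L)]
    if (any(startsWith(block, "LOCUS"))) recs[[length(recs) + 1L]] <- block
  }
  out <- lapply(recs, .parse_genbank_record)
  genes <- do.call(rbind, out)
  if (is.null(genes) || nrow(genes) == 0L) {
    stop("no annotated gene/CDS features found in ", path)
  }
  .build_gene_db(genes, read_length)
}

# Parse one GenBank record into a data.frame of raw feature coordinates plus
# the contig sequence (kept in an attribute).
.parse_genbank_record <- function(block) {
  locus <- strsplit(trimws(block[startsWith(block, "LOCUS")][1]), "\\s+")[[1]]
  contig_id <- locus[2]
  ori <- which(startsWith(block, "ORIGIN"))
  if (!length(ori)) stop("GenBank record without ORIGIN sequence: ", contig_id)
  seq_lines <- block[(ori[1] + 1L):length(block)]
  contig <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_start <- which(startsWith(block, "FEATURES"))
  feats <- data.frame(key = character(), start = integer(), end = integer(),
                      strand = character(), id = character(),
                      pseudo = logical(), stringsAsFactors = FALSE)
  if (length(feat_start)) {
    flines <- block[(feat_start[1] + 1L):(ori[1] - 1L)]
    # feature headers have their key in columns 6-20, qualifiers start with /
    is_hdr <- grepl("^\\s{2,8}\\S", flines) & !grepl("^\\s*/", flines)
    idx <- which(is_hdr)
    for (k in seq_along(idx)) {
      hdr <- flines[idx[k]]
      body_end <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
      body <- flines[seq.int(idx[k], body_end)]
      key <- sub("^\\s*(\\S+).*", "\\1", hdr)
      if (!key %in% c("CDS", "gene")) next
      loc <- sub("^\\s*\\S+\\s+", "", hdr)
      # location may continue onto lines that are not qualifiers
      cont <- body[-1][!grepl("^\\s*/", body[-1])]
      if (length(cont)) loc <- paste0(loc, paste(trimws(cont), collapse = ""))
      loc <- gsub("\\s", "", loc)
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("join|order", loc)) {
        warning("skipping compound-location feature in ", contig_id, ": ", loc)
        next
      }
      m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
      if (length(m) != 3L) {
        if (grepl("^\\d+$", loc)) m <- c(loc, loc, loc) else next
      }
      quals <- body[grepl("^\\s*/", body)]
      pseudo <- any(grepl("^\\s*/pseudo\\s*$", quals))
      id <- NA_character_
      for (q in c("locus_tag", "gene")) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (length(hit)) {
          id <- gsub("\"", "", sub(paste0("^\\s*/", q, "="), "", hit[1]))
          break
        }
      }
      feats <- rbind(feats, data.frame(
        key = key, start = as.integer(m[2]), end = as.integer(m[3]),
        strand = strand, id = id, pseudo = pseudo, stringsAsFactors = FALSE))
    }
  }
  if (nrow(feats)) {
    use_key <- if (any(feats$key == "CDS")) "CDS" else "gene"
    feats <- feats[feats$key == use_key & !feats$pseudo, , drop = FALSE]
  }
  if (!nrow(feats)) return(NULL)
  feats$contig_id <- contig_id
  feats$contig_len <- nchar(contig)
  missing_id <- is.na(feats$id)
  feats$id[missing_id] <- sprintf("%s_g%03d", contig_id, which(missing_id))
  attr(feats, "contig") <- contig
  feats$contig_seq <- contig
  feats
}

.build_gene_db <- function(feats, read_length) {
  L <- pmin(read_length, feats$start - 1L)
  R <- pmin(read_length, feats$contig_len - feats$end)
  ext <- substring(feats$contig_seq, feats$start - L, feats$end + R)
  db <- data.frame(
    gene_id = feats$id,
    contig_id = feats$contig_id,
    gene_start = feats$start,
    gene_end = feats$end,
    strand = feats$strand,
    flank_left = as.integer(L),
    flank_right = as.integer(R),
    core_len = as.integer(feats$end - feats$start + 1L),
    ext_seq = ext,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(db$gene_id)) {
    db$gene_id <- make.unique(db$gene_id, sep = "_dup")
  }
  class(db) <- c("gene_db", "data.frame")
  db
}

#' Core (un-flanked) gene sequences of a gene database
#'
#' @param db A `gene_db` from [read_genbank_genes()] or [read_gene_db()].
#' @return Named character vector of core gene sequences.
#' @export
core_seq <- function(db) {
  setNames(substring(db$ext_seq, db$flank_left + 1L,
                     db$flank_left + db$core_len), db$gene_id)
}

# FASTA header carrying the metadata needed to recover core boundaries.
db_names <- function(db) {
  sprintf("%s|%s|%d|%d|%d|%d", db$gene_id, db$contig_id, db$gene_start,
          db$gene_end, db$flank_left, db$flank_right)
}

#' Serialize a gene database as a mapping FASTA
#'
#' One record per flank-extended gene; the header
#' `gene_id|contig_id|start|end|flank_left|flank_right` round-trips through
#' [read_gene_db()] so downstream stages can recover core boundaries.
#'
#' @param db A `gene_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_gene_db <- function(db, path) {
  if (is.null(db) || nrow(db) == 0L) stop("empty gene database")
  seqs <- Biostrings::DNAStringSet(setNames(db$ext_seq, db_names(db)))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read back a gene-database FASTA written by [write_gene_db()]
#'
#' @param path FASTA path.
#' @return A `gene_db` data.frame.
#' @export
read_gene_db <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stop("not a gene-database FASTA (bad header): ", path)
  m <- do.call(rbind, parts)
  db <- data.frame(
    gene_id = m[, 1], contig_id = m[, 2],
    gene_start = as.integer(m[, 3]), gene_end = as.integer(m[, 4]),
    strand = "+",
    flank_left = as.integer(m[, 5]), flank_right = as.integer(m[, 6]),
    core_len = as.integer(m[, 4]) - as.integer(m[, 3]) + 1L,
    ext_seq = as.character(seqs),
    stringsAsFactors = FALSE
  )
  class(db) <- c("gene_db", "data.frame")
  db
}
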