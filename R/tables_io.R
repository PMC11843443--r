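# Readers and writers for the external tables the pipeline touches, plus
# longest-transcript gene representation. Malformed lines abort with a
# line-numbered error rather than being skipped: silent skipping would
# corrupt the counts that every downstream statistic depends on.

#' Read a gene-age table
#'
#' Tab-separated file with header `gene_id`, `branch`, `biotype`,
#' `chromosome`. Branch labels outside [branch_labels()] and biotypes other
#' than `protein_coding`/`ncRNA` are rejected, as are duplicate gene ids.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `gene_id`, `branch` (factor on the
#'   ordered branch scale), `biotype`, `chromosome`.
#' @export
read_age_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file (no header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("gene_id", "branch", "biotype", "chromosome")
  if (!identical(header, expected)) {
    stop("bad header in ", path, "; expected: ",
         paste(expected, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(data.frame(gene_id = character(),
                      branch = factor(character(), levels = branch_labels()),
                      biotype = character(), chromosome = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    ln <- which(nf != 4)[1] + 1L
    stop("malformed row at line ", ln, " of ", path,
         " (expected 4 tab-separated fields, got ", nf[ln - 1L], ")")
  }
  m <- do.call(rbind, fields)
  df <- data.frame(gene_id = m[, 1], branch = m[, 2], biotype = m[, 3],
                   chromosome = m[, 4], stringsAsFactors = FALSE)
  bad_branch <- !df$branch %in% branch_labels()
  if (any(bad_branch)) {
    ln <- which(bad_branch)[1] + 1L
    stop("unknown branch label '", df$branch[ln - 1L], "' at line ", ln,
         " of ", path)
  }
  bad_bio <- !df$biotype %in% c("protein_coding", "ncRNA")
  if (any(bad_bio)) {
    ln <- which(bad_bio)[1] + 1L
    stop("unknown biotype '", df$biotype[ln - 1L], "' at line ", ln,
         " of ", path)
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(df$gene_id[dup]), collapse = ", "))
  }
  df$branch <- factor(df$branch, levels = branch_labels())
  df
}

#' Write a gene-age table
#'
#' Inverse of [read_age_table()]; emits a header line.
#'
#' @param ages data.frame as returned by [read_age_table()].
#' @param path Output path.
#' @export
write_age_table <- function(ages, path) {
  stopifnot(all(c("gene_id", "branch", "biotype", "chromosome")
                %in% names(ages)))
  out <- ages[, c("gene_id", "branch", "biotype", "chromosome")]
  out$branch <- as.character(out$branch)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Header-name normalization for localization tables: case-insensitive,
# spaces/slashes/dashes collapsed to underscore.
.normalize_compartment_header <- function(x) {
  key <- tolower(gsub("[ /.-]+", "_", trimws(x)))
  canon <- compartments()
  names(canon) <- tolower(canon)
  out <- canon[key]
  ifelse(is.na(out), x, out)
}

#' Read a localization probability table
#'
#' CSV with one protein-id column (named e.g. `Protein_ID`, `ACC` or `ID`)
#' and one numeric probability column per compartment in the canonical
#' nine-compartment vocabulary ([compartments()]); header synonyms are
#' normalized case-insensitively. A plant-specific `Plastid` column, if
#' present, is silently dropped. Probabilities outside [0, 1] are rejected.
#'
#' @param path Path to the CSV file.
#' @return data.frame with `protein_id` plus the nine compartment columns,
#'   in canonical order.
#' @export
read_localization_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("localization table needs an id column plus ",
                         "compartment columns: ", path)
  nm <- names(df)
  id_candidates <- c("protein_id", "acc", "id", "protein")
  id_col <- which(tolower(nm) %in% id_candidates)[1]
  if (is.na(id_col)) id_col <- 1L
  names(df) <- .normalize_compartment_header(nm)
  names(df)[id_col] <- "protein_id"
  # drop the plant-specific compartment
  plastid <- which(tolower(names(df)) == "plastid")
  if (length(plastid) > 0) df <- df[, -plastid, drop = FALSE]
  missing <- setdiff(compartments(), names(df))
  if (length(missing) > 0) {
    stop("missing compartment column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  out <- df[, c("protein_id", compartments())]
  for (cc in compartments()) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) stop("non-numeric probability in column ", cc)
    if (any(v < 0 | v > 1)) {
      stop("probability outside [0, 1] in column ", cc,
           " (first offending row ", which(v < 0 | v > 1)[1], ")")
    }
    out[[cc]] <- v
  }
  if (anyDuplicated(out$protein_id)) {
    stop("duplicate protein_id in ", path)
  }
  out
}

#' Write a localization probability table
#' @param loc data.frame as returned by [read_localization_table()].
#' @param path Output path.
#' @export
write_localization_table <- function(loc, path) {
  stopifnot(all(c("protein_id", compartments()) %in% names(loc)))
  utils::write.csv(loc[, c("protein_id", compartments())], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the longest transcript per gene
#'
#' Transcript length is the sum of exon lengths (GTF coordinates, 1-based
#' inclusive). Ties are broken by the lexicographically smallest
#' transcript id so the choice is reproducible.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `chromosome`, `start`, `end`, `strand` (one row per exon).
#' @return Named character vector mapping `gene_id` to the representative
#'   `transcript_id`; empty input yields an empty mapping.
#' @export
select_longest_transcript <- function(exons) {
  needed <- c("transcript_id", "gene_id", "start", "end")
  stopifnot(all(needed %in% names(exons)))
  if (nrow(exons) == 0) return(setNames(character(), character()))
  len <- exons$end - exons$start + 1
  if (any(len <= 0)) stop("exon with non-positive length")
  tl <- tapply(len, exons$transcript_id, sum)
  tg <- exons$gene_id[match(names(tl), exons$transcript_id)]
  df <- data.frame(transcript_id = names(tl), gene_id = tg,
                   length = as.numeric(tl), stringsAsFactors = FALSE)
  # order: gene, decreasing length, then transcript id; first row per gene wins
  df <- df[order(df$gene_id, -df$length, df$transcript_id), ]
  keep <- df[!duplicated(df$gene_id), ]
  setNames(keep$transcript_id, keep$gene_id)
}

#' Read exon models from a GTF annotation
#'
#' Only `exon` features are consumed; attributes `gene_id` and
#' `transcript_id` are required.
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns `transcript_id`, `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`.
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(transcript_id = gr$transcript_id, gene_id = gr$gene_id,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a protein FASTA
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are uppercased and trailing `*` stop characters are stripped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence in ", path, ": ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write a protein FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a paralog pair table
#'
#' Tab-separated with header `gene_id`, `paralog_id`. Pair polarity (which
#' member is parental) is established later from gene ages.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `gene_id`, `paralog_id`.
#' @export
read_paralog_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "paralog_id") %in% names(df))) {
    stop("paralog table needs columns gene_id, paralog_id: ", path)
  }
  df[, c("gene_id", "paralog_id")]
}

#' Write a paralog pair table
#' @param pairs data.frame with columns `gene_id`, `paralog_id`.
#' @param path Output path.
#' @export
write_paralog_table <- function(pairs, path) {
  stopifnot(all(c("gene_id", "paralog_id") %in% names(pairs)))
  write.table(pairs[, c("gene_id", "paralog_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix
#'
#' TSV with a `gene_id` column and one 0/1 column per outgroup clade.
#'
#' @param path Path to the TSV file.
#' @return Logical matrix, genes as rows (rownames), clades as columns.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("presence matrix needs gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- df$gene_id
  m
}

#' Write a presence/absence matrix
#' @param presence Logical matrix with gene rownames and clade colnames.
#' @param path Output path.
#' @export
write_presence_matrix <- function(presence, path) {
  df <- data.frame(gene_id = rownames(presence),
                   presence * 1L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
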