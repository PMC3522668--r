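#' @importFrom stats sd var rnorm runif rbinom rpois rexp rmultinom setNames
#'   p.adjust anova lm pchisq chisq.test kruskal.test wilcox.test fisher.test
#'   nlminb uniroot quantile optimize ave
#' @importFrom utils head tail read.delim write.table combn
NULL

# ---- locus alignments --------------------------------------------------------

#' Construct a locus alignment
#'
#' A `locus_alignment` holds the aligned haplotype (allele) sequences of one
#' locus, the alignment length, and the bookkeeping of indel columns: any
#' column in which at least one haplotype carries a gap (`-`) is flagged as an
#' indel column and excluded from all pairwise nucleotide statistics
#' (complete deletion).  Allele identity, by contrast, retains the gap
#' pattern, so alleles that differ only by an indel are distinct.
#'
#' @param locus_id single character locus name.
#' @param allele_ids character vector of unique haplotype/allele names.
#' @param seqs character vector of aligned IUPAC DNA sequences (may contain
#'   `-`), one per allele, all the same length.
#' @return An object of class `locus_alignment` with fields `locus_id`,
#'   `allele_ids`, `seqs`, `alignment_length`, `indel_columns` (0-based
#'   internally stored as 1-based R indices), and `analyzed_sites`.
#' @export
locus_alignment <- function(locus_id, allele_ids, seqs) {
  allele_ids <- as.character(allele_ids)
  seqs <- toupper(as.character(seqs))
  if (length(allele_ids) != length(seqs))
    stop("allele_ids and seqs must have equal length")
  if (length(seqs) < 1L) stop("alignment must contain at least one record")
  if (anyDuplicated(allele_ids))
    stop("duplicate allele ids in alignment for locus ", locus_id)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment for locus ", locus_id,
         ": sequence lengths ", paste(unique(lens), collapse = ", "))
  L <- lens[[1L]]
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  indel_cols <- which(apply(mat == "-", 2L, any))
  structure(list(
    locus_id = locus_id,
    allele_ids = allele_ids,
    seqs = seqs,
    seq_matrix = mat,
    alignment_length = L,
    indel_columns = as.integer(indel_cols),
    analyzed_sites = L - length(indel_cols)
  ), class = "locus_alignment")
}

#' Read a FASTA alignment as a locus_alignment
#'
#' @param path FASTA file.
#' @param locus_id locus name to attach.
#' @return a [locus_alignment()].
#' @export
read_locus_alignment <- function(path, locus_id) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop("no FASTA records in ", path)
  chr <- vapply(as.character(dna), function(x) paste(x, collapse = ""), "")
  locus_alignment(locus_id, names(dna), chr)
}

#' Write a locus_alignment as FASTA
#' @param aln a locus_alignment.
#' @param path output file.
#' @export
write_locus_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$allele_ids), tolower(aln$seqs)))
  writeLines(lines, path)
  invisible(path)
}

# ---- genotype tables ---------------------------------------------------------

#' Construct a genotype table
#'
#' Calls are stored per locus as a list with one entry per individual:
#' \itemize{
#'   \item microsatellite: length-2 character vector of allele labels (a
#'     homozygote repeats the label); a half-locus call is `c(allele, NA)`;
#'     missing is `character(0)`.
#'   \item sequence_diploid: 1 or 2 distinct allele ids (1 = homozygote).
#'   \item sequence_multicopy: 1--4 distinct allele ids.
#' }
#'
#' @param individuals character vector of individual ids.
#' @param loci data.frame with columns `locus_id` and `kind` (one of
#'   `"microsatellite"`, `"sequence_diploid"`, `"sequence_multicopy"`).
#' @param calls named list (by locus_id) of per-individual call lists.
#' @param alignments optional named list of [locus_alignment()] objects used
#'   to validate sequence-locus allele ids.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, calls, alignments = NULL) {
  individuals <- as.character(individuals)
  stopifnot(is.data.frame(loci), all(c("locus_id", "kind") %in% names(loci)))
  if (!all(loci$kind %in% c("microsatellite", "sequence_diploid",
                            "sequence_multicopy")))
    stop("unknown locus kind")
  if (!setequal(names(calls), loci$locus_id))
    stop("calls must be named by locus_id")
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[[i]]
    kind <- loci$kind[[i]]
    cl <- calls[[lid]]
    if (length(cl) != length(individuals))
      stop("locus ", lid, ": one call per individual required")
    for (j in seq_along(cl)) {
      cc <- cl[[j]]
      if (length(cc) == 0L) next
      nd <- length(unique(cc[!is.na(cc)]))
      if (kind == "microsatellite") {
        if (length(cc) != 2L)
          stop("locus ", lid, ": microsatellite calls are allele pairs")
      } else if (kind == "sequence_diploid") {
        if (any(is.na(cc))) {
          if (length(cc) != 2L || nd != 1L)
            stop("locus ", lid, ": malformed half-locus call")
        } else if (nd < 1L || nd > 2L || length(cc) != nd) {
          stop("locus ", lid, ": sequence_diploid calls have 1-2 distinct ids")
        }
      } else {
        if (any(is.na(cc)) || nd < 1L || nd > 4L || length(cc) != nd)
          stop("locus ", lid,
               ": sequence_multicopy calls have 1-4 distinct ids")
      }
      if (!is.null(alignments) && !is.null(alignments[[lid]])) {
        bad <- setdiff(cc[!is.na(cc)], alignments[[lid]]$allele_ids)
        if (length(bad))
          stop("locus ", lid, ": allele id(s) not in alignment: ",
               paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(individuals = individuals, loci = loci, calls = calls,
                 alignments = alignments),
            class = "genotype_table")
}

#' Read a delimited genotype table
#'
#' One row per individual (first column `individual`), one column per locus.
#' Microsatellite and diploid-sequence cells are `a/b` (a half-locus call is
#' `a/NA`); multicopy cells are comma-joined allele ids; a bare missing code
#' (default `"NA"`) marks a missing call.
#'
#' @param path TSV file.
#' @param schema data.frame with `locus_id` and `kind` for every locus column.
#' @param missing_code string marking missing data.
#' @param alignments optional named list of alignments for id validation.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, schema, missing_code = "NA",
                                alignments = NULL) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (names(df)[[1L]] != "individual")
    stop("first column must be 'individual'")
  missing_cols <- setdiff(schema$locus_id, names(df))
  if (length(missing_cols))
    stop("locus column(s) missing: ", paste(missing_cols, collapse = ", "))
  calls <- list()
  for (i in seq_len(nrow(schema))) {
    lid <- schema$locus_id[[i]]
    kind <- schema$kind[[i]]
    calls[[lid]] <- lapply(df[[lid]], function(cell) {
      parse_call(cell, kind, missing_code)
    })
  }
  genotype_table(df$individual, schema, calls, alignments)
}

parse_call <- function(cell, kind, missing_code = "NA") {
  cell <- trimws(cell)
  if (!nzchar(cell) || cell == missing_code) return(character(0))
  if (kind == "sequence_multicopy") {
    ids <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
    ids <- unique(ids[nzchar(ids)])
    if (length(ids) > 4L)
      stop("multicopy call with more than 4 alleles: ", cell)
    return(ids)
  }
  parts <- trimws(strsplit(cell, "/", fixed = TRUE)[[1L]])
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L) stop("malformed diploid call: ", cell)
  parts[parts == missing_code] <- NA_character_
  if (all(is.na(parts))) return(character(0))
  if (any(is.na(parts))) parts <- c(parts[!is.na(parts)], NA_character_)
  if (kind == "sequence_diploid" && !any(is.na(parts)))
    parts <- unique(parts)
  parts
}

#' Write a genotype table as TSV
#' @param gt genotype_table.
#' @param path output file.
#' @param missing_code missing marker.
#' @export
write_genotype_table <- function(gt, path, missing_code = "NA") {
  cols <- list(individual = gt$individuals)
  for (i in seq_len(nrow(gt$loci))) {
    lid <- gt$loci$locus_id[[i]]
    kind <- gt$loci$kind[[i]]
    cols[[lid]] <- vapply(gt$calls[[lid]], function(cc) {
      if (length(cc) == 0L) return(missing_code)
      cc[is.na(cc)] <- missing_code
      if (kind == "sequence_multicopy") paste(cc, collapse = ",")
      else paste(cc, collapse = "/")
    }, "")
  }
  write.table(as.data.frame(cols, check.names = FALSE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- population maps ---------------------------------------------------------

#' Read a population map (TSV: individual, population)
#' @param path TSV file with columns `individual` and `population`.
#' @return named character vector, individual -> population label.
#' @export
read_population_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  setNames(df$population, df$individual)
}

#' Write a population map
#' @param popmap named character vector.
#' @param path output file.
#' @export
write_population_map <- function(popmap, path) {
  write.table(data.frame(individual = names(popmap), population = popmap),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_popmap <- function(gt, popmap, n_pops_exact = NULL) {
  miss <- setdiff(gt$individuals, names(popmap))
  if (length(miss))
    stop("individuals without population label: ", paste(miss, collapse = ", "))
  pops <- unique(popmap[gt$individuals])
  if (!is.null(n_pops_exact) && length(pops) != n_pops_exact)
    stop("expected ", n_pops_exact, " populations, found ", length(pops))
  pops
}

# ---- summary tables ----------------------------------------------------------

#' Write summary tables as TSV files
#'
#' Writes one TSV per table (named list of data.frames) with numeric columns
#' rounded to 6 decimals, so write -> read round-trips losslessly at that
#' precision.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_summary_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) round(x, 6L))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a summary table written by [write_summary_tables()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_summary_table <- function(path) {
  read.delim(path, check.names = FALSE)
}

# ---- gene-copy helpers -------------------------------------------------------

#' Expand calls at a locus into gene copies
#'
#' A half-locus call contributes its single scored allele (and one fewer
#' copy); missing calls contribute nothing; a sequence-locus homozygote
#' contributes two copies.  Multicopy calls follow the counting rule in
#' [allele_frequencies()] and are not expanded here.
#'
#' @param gt [genotype_table()].
#' @param locus locus id.
#' @param individuals subset of individuals (default all).
#' @return character vector of allele labels, one per gene copy.
#' @export
gene_copies <- function(gt, locus, individuals = gt$individuals) {
  kind <- gt$loci$kind[gt$loci$locus_id == locus]
  if (length(kind) != 1L) stop("unknown locus ", locus)
  idx <- match(individuals, gt$individuals)
  if (anyNA(idx)) stop("unknown individual(s)")
  out <- lapply(gt$calls[[locus]][idx], function(raw) {
    cc <- raw[!is.na(raw)]
    if (length(cc) == 0L) return(character(0))
    # a sequence_diploid homozygote is stored as a single id = two copies;
    # a half-locus call (allele + NA) contributes its one scored allele
    if (kind == "sequence_diploid" && length(raw) == 1L) return(rep(cc, 2L))
    cc
  })
  unlist(out, use.names = FALSE)
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 94906249 * 7919 + k * 104729 + 1) %%
               2147483647)
}
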