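# Readers for every external artifact the pipeline consumes. Each reader
# normalizes a tool dialect (FASTA, Foldseek/MMseqs2 tabular output, GFF3,
# PDB/mmCIF, NCBI taxdump) into the plain data frames and S3 objects used by
# the rest of the package.

#' Read a protein FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a data frame with one row
#' per record. The first whitespace-delimited token of each header is the
#' protein id; the remainder is kept as the description. Residues are
#' upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `protein_id`, `description`, `residues`,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 terminase", "MKL", ">p2", "avf"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) ph_stop("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) ph_stop("FASTA parse error at line 1: file is empty")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    ph_stop("FASTA parse error at line %d: expected a '>' header", first)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) ph_stop("FASTA parse error at line 1: no records")
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids))) {
    ph_stop("FASTA parse error: empty id in header '%s'", headers[!nzchar(ids)][1L])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    ph_stop("duplicate protein id(s) in FASTA: %s", paste(unique(dup), collapse = ", "))
  }
  residues <- toupper(as.character(seqs))
  if (any(nchar(residues) == 0L)) {
    ph_stop("empty sequence for id(s): %s", paste(ids[nchar(residues) == 0L], collapse = ", "))
  }
  data.frame(protein_id = unname(ids), description = unname(desc),
             residues = unname(residues), stringsAsFactors = FALSE)
}

#' Default column map for tabular alignment files
#'
#' Matches the Foldseek output convention
#' `--format-output query,target,fident,qcov,tcov,evalue,alntmscore,lddt,theader,taxid`.
#' The map is a named integer vector: field name to 1-based column index.
#' Fields `query_id` through `evalue` are required; the rest are optional and
#' become `NA` when their column is absent from the file.
#'
#' @return Named integer vector mapping alignment fields to column indices.
#' @export
alignment_columns <- function() {
  c(query_id = 1L, target_id = 2L, seq_identity = 3L, query_cov = 4L,
    target_cov = 5L, evalue = 6L, tm_score = 7L, lddt = 8L,
    target_name = 9L, target_taxid = 10L, target_db = 11L)
}

.aln_required <- c("query_id", "target_id", "seq_identity", "query_cov",
                   "target_cov", "evalue")
.aln_fractional <- c("seq_identity", "query_cov", "target_cov", "tm_score", "lddt")
.db_tags <- c("PDB", "AFDB_SwissProt", "AFDB", "counter_defense", "other")

#' Read a tab-separated pairwise alignment table
#'
#' Reads Foldseek/MMseqs2-style tabular alignment output into a validated
#' data frame of alignment records. Columns are located through `column_map`
#' so any `--format-output` layout can be consumed. Optional fields whose
#' column is missing from the file (or unmapped) are set to `NA`.
#'
#' Fractional fields (`seq_identity`, `query_cov`, `target_cov`, `tm_score`,
#' `lddt`) must lie in \[0,1\] and E-values must be non-negative; violations
#' raise an error naming the offending row. Decimal points are mandatory
#' (locale-independent parsing) and scientific notation is accepted.
#'
#' @param path Path to a tab-separated file without a header row.
#' @param column_map Named integer vector as returned by
#'   [alignment_columns()]; entries may be dropped to mark fields absent.
#' @return Data frame with columns `query_id`, `target_id`, `seq_identity`,
#'   `query_cov`, `target_cov`, `evalue`, `tm_score`, `lddt`, `target_name`,
#'   `target_db`, `target_taxid`.
#' @export
read_alignment_table <- function(path, column_map = alignment_columns()) {
  if (!file.exists(path)) ph_stop("alignment file not found: %s", path)
  missing_req <- setdiff(.aln_required, names(column_map))
  if (length(missing_req) > 0L) {
    ph_stop("column_map lacks required field(s): %s", paste(missing_req, collapse = ", "))
  }
  raw <- tryCatch(
    read.delim(path, header = FALSE, sep = "\t", quote = "",
               colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    return(empty_alignment_table())
  }
  n <- nrow(raw)
  get_col <- function(field) {
    idx <- column_map[[field]]
    if (is.null(idx) || is.na(idx) || idx > ncol(raw)) {
      if (field %in% .aln_required) {
        ph_stop("alignment file %s has %d columns but required field '%s' maps to column %d",
                path, ncol(raw), field, if (is.null(idx)) NA_integer_ else idx)
      }
      return(rep(NA_character_, n))
    }
    raw[[idx]]
  }
  num_col <- function(field) {
    x <- get_col(field)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad) > 0L) {
      ph_stop("alignment row %d: field '%s' is not numeric ('%s')", bad[1L], field, x[bad[1L]])
    }
    out
  }
  aln <- data.frame(
    query_id = get_col("query_id"),
    target_id = get_col("target_id"),
    seq_identity = num_col("seq_identity"),
    query_cov = num_col("query_cov"),
    target_cov = num_col("target_cov"),
    evalue = num_col("evalue"),
    tm_score = num_col("tm_score"),
    lddt = num_col("lddt"),
    target_name = get_col("target_name"),
    target_db = normalize_db_tag(get_col("target_db")),
    target_taxid = suppressWarnings(as.integer(get_col("target_taxid"))),
    stringsAsFactors = FALSE)
  validate_alignments(aln)
  aln
}

empty_alignment_table <- function() {
  data.frame(query_id = character(), target_id = character(),
             seq_identity = numeric(), query_cov = numeric(),
             target_cov = numeric(), evalue = numeric(),
             tm_score = numeric(), lddt = numeric(),
             target_name = character(), target_db = character(),
             target_taxid = integer(), stringsAsFactors = FALSE)
}

normalize_db_tag <- function(x) {
  x <- as.character(x)
  known <- match(tolower(x), tolower(.db_tags))
  out <- ifelse(is.na(known), ifelse(is.na(x) | !nzchar(x), NA_character_, "other"),
                .db_tags[known])
  out
}

#' Validate a data frame of alignment records
#'
#' Enforces the alignment-record invariants: non-empty query/target ids,
#' fractional fields within \[0,1\], non-negative E-values.
#'
#' @param aln Data frame as produced by [read_alignment_table()].
#' @return `aln`, invisibly, after validation.
#' @export
validate_alignments <- function(aln) {
  if (nrow(aln) == 0L) return(invisible(aln))
  bad_id <- which(is.na(aln$query_id) | !nzchar(aln$query_id) |
                  is.na(aln$target_id) | !nzchar(aln$target_id))
  if (length(bad_id) > 0L) ph_stop("alignment row %d: empty query or target id", bad_id[1L])
  for (field in .aln_fractional) {
    v <- aln[[field]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0L) {
      ph_stop("alignment row %d: field '%s' = %g outside [0,1]", bad[1L], field, v[bad[1L]])
    }
  }
  bad_e <- which(!is.na(aln$evalue) & aln$evalue < 0)
  if (length(bad_e) > 0L) {
    ph_stop("alignment row %d: negative evalue %g", bad_e[1L], aln$evalue[bad_e[1L]])
  }
  invisible(aln)
}

#' Read a two-column cluster TSV into a clustering
#'
#' Reads the MMseqs2/Foldseek cluster dialect (`representative TAB member`,
#' one row per member, representatives listed as their own members) and
#' validates that the rows describe a partition. A representative that is not
#' listed as its own member is added to its cluster.
#'
#' @param path Path to the TSV file. An empty file yields an empty clustering.
#' @param provenance `"sequence"` or `"structure"`; recorded on the object.
#' @return A [new_clustering()] object.
#' @export
read_cluster_tsv <- function(path, provenance = "sequence") {
  if (!file.exists(path)) ph_stop("cluster file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_clustering(list(), provenance = provenance))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) ph_stop("cluster file line %d: expected two tab-separated columns", bad[1L])
  rep_id <- vapply(parts, `[[`, "", 1L)
  member <- vapply(parts, `[[`, "", 2L)
  clusters <- split(member, rep_id)
  clusters <- lapply(names(clusters), function(r) sort(unique(c(r, clusters[[r]]))))
  names(clusters) <- sort(unique(rep_id))
  new_clustering(clusters, provenance = provenance)
}

#' Write a clustering as a two-column TSV
#'
#' Emits the MMseqs2-compatible `representative TAB member` dialect, with the
#' representative listed as its own member and deterministic (lexicographic)
#' ordering of clusters and members.
#'
#' @param clustering A [new_clustering()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clustering, path) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  reps <- sort(names(clustering$clusters))
  rows <- unlist(lapply(reps, function(r) {
    paste(r, sort(clustering$clusters[[r]]), sep = "\t")
  }))
  writeLines(rows %||% character(), path)
  invisible(path)
}

#' Extract per-residue pLDDT from a model coordinate file
#'
#' Reads a PDB or mmCIF file whose B-factor column stores the per-residue
#' predicted confidence (pLDDT, 0-100) of a structure model, the convention
#' used by AlphaFold model files. One value is taken per residue, from the CA
#' atom when present, otherwise from the residue's first atom. Values outside
#' \[0,100\] are clamped with a warning.
#'
#' @param path Path to a `.pdb`, `.cif` or `.mmcif` file.
#' @param model_id Identifier for the model; defaults to the file name
#'   without extension.
#' @return An object of class `structure_model`: a list with `model_id` and
#'   numeric vector `plddt` (one value per residue, chain order).
#' @export
read_plddt <- function(path, model_id = NULL) {
  if (!file.exists(path)) ph_stop("model file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch({
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path)
  }, error = function(e) ph_stop("cannot parse model file %s: %s", path, conditionMessage(e)))
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0L) ph_stop("model file %s contains no residues", path)
  ins <- atoms$insert
  if (is.null(ins)) ins <- ""
  ins[is.na(ins)] <- ""
  res_key <- paste(atoms$chain, atoms$resno, ins, sep = "|")
  keys <- unique(res_key)  # file order
  plddt <- vapply(keys, function(k) {
    idx <- which(res_key == k)
    ca <- idx[atoms$elety[idx] == "CA"]
    pick <- if (length(ca) > 0L) ca[1L] else idx[1L]
    as.numeric(atoms$b[pick])
  }, numeric(1))
  out_of_range <- which(plddt < 0 | plddt > 100)
  if (length(out_of_range) > 0L) {
    ph_warn("%d residue pLDDT value(s) outside [0,100] in %s; clamped",
            length(out_of_range), path)
    plddt <- pmin(pmax(plddt, 0), 100)
  }
  structure(list(model_id = model_id %||% tools::file_path_sans_ext(basename(path)),
                 plddt = unname(plddt)),
            class = "structure_model")
}

#' Read product annotations from a GFF3 file
#'
#' Extracts the `product` attribute of every CDS feature. The protein id is
#' taken from the `ID` attribute, falling back to `locus_tag`. A CDS without
#' a product attribute gets `product = ""`, which downstream rate
#' calculations count as unannotated. Attribute values are URL-decoded;
#' coordinates are ignored (only the id-to-product mapping is needed).
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `protein_id`, `product`, `source`
#'   (always `"sequence"`), in file order.
#' @export
read_products_from_gff <- function(path) {
  if (!file.exists(path)) ph_stop("GFF file not found: %s", path)
  gff <- tryCatch(
    rtracklayer::readGFF(path, columns = c("type"),
                         tags = c("ID", "locus_tag", "product")),
    error = function(e) ph_stop("cannot parse GFF file %s: %s", path, conditionMessage(e)))
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    return(data.frame(protein_id = character(), product = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  take <- function(col) {
    if (col %in% names(cds)) as.character(cds[[col]]) else rep(NA_character_, nrow(cds))
  }
  id <- take("ID")
  lt <- take("locus_tag")
  id <- ifelse(is.na(id) | !nzchar(id), lt, id)
  bad <- which(is.na(id) | !nzchar(id))
  if (length(bad) > 0L) {
    ph_stop("GFF CDS feature %d has neither ID nor locus_tag attribute", bad[1L])
  }
  product <- take("product")
  product <- ifelse(is.na(product), "", product)
  product <- vapply(product, function(p) URLdecode(p), "", USE.NAMES = FALSE)
  data.frame(protein_id = id, product = product, source = "sequence",
             stringsAsFactors = FALSE)
}

# -- NCBI taxdump -----------------------------------------------------------
# No installed R package reads the raw nodes.dmp/names.dmp dialect, so the
# pipe-delimited format is parsed here directly (fields separated by
# "\t|\t", rows terminated by "\t|").

split_dmp <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Read an NCBI-taxdump-style taxonomy
#'
#' Parses `nodes.dmp` (taxid, parent taxid, rank) and `names.dmp` (scientific
#' names only) and returns a validated taxonomy tree. The root is the unique
#' node whose parent is itself; orphan parents, multiple roots and cycles are
#' rejected.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @return A [new_taxonomy_tree()] object.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  for (p in c(nodes_path, names_path)) {
    if (!file.exists(p)) ph_stop("taxdump file not found: %s", p)
  }
  nl <- readLines(nodes_path, warn = FALSE)
  nl <- nl[nzchar(trimws(nl))]
  if (length(nl) == 0L) ph_stop("empty nodes.dmp: %s", nodes_path)
  np <- split_dmp(nl)
  bad <- which(vapply(np, length, 1L) < 3L)
  if (length(bad) > 0L) ph_stop("nodes.dmp line %d: expected at least 3 fields", bad[1L])
  taxid <- as.integer(trimws(vapply(np, `[[`, "", 1L)))
  parent <- as.integer(trimws(vapply(np, `[[`, "", 2L)))
  rank <- trimws(vapply(np, `[[`, "", 3L))
  if (anyNA(taxid) || anyNA(parent)) ph_stop("nodes.dmp: non-integer taxid or parent")

  ml <- readLines(names_path, warn = FALSE)
  ml <- ml[nzchar(trimws(ml))]
  mp <- split_dmp(ml)
  keep <- vapply(mp, function(f) length(f) >= 4L && trimws(f[[4L]]) == "scientific name", TRUE)
  mp <- mp[keep]
  name_taxid <- as.integer(trimws(vapply(mp, `[[`, "", 1L)))
  name_txt <- trimws(vapply(mp, `[[`, "", 2L))
  name <- name_txt[match(taxid, name_taxid)]
  name[is.na(name)] <- paste0("taxid_", taxid[is.na(name)])

  new_taxonomy_tree(taxid = taxid, parent = parent, rank = rank, name = name)
}
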