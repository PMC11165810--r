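#' Pairwise association tables with a shared entity vocabulary
#'
#' A `pair_tables` object bundles the three two-column relation tables that
#' feed event construction — drug–target, drug–disease and target–disease —
#' together with an entity vocabulary assigning every drug, target and
#' disease identifier a contiguous 0-based integer index. Identifiers are
#' indexed in lexicographic order so that all downstream indices (and hence
#' one-hot feature columns) are reproducible from the input tables alone.
#'
#' @param drug_target,drug_disease,target_disease Data frames with two
#'   character columns (source identifier, destination identifier). Rows are
#'   deduplicated; column names are ignored.
#' @return A `pair_tables` object: a list with tibbles `drug_target`
#'   (columns `drug`, `target`), `drug_disease` (`drug`, `disease`),
#'   `target_disease` (`target`, `disease`) and `vocab`
#'   (`kind`, `id`, `index`).
#' @examples
#' pt <- pair_tables(
#'   drug_target    = data.frame(a = "X1", b = "Y1"),
#'   drug_disease   = data.frame(a = "X1", b = c("Z1", "Z2")),
#'   target_disease = data.frame(a = "Y1", b = c("Z1", "Z2"))
#' )
#' pt$vocab
#' @export
pair_tables <- function(drug_target, drug_disease, target_disease) {
  dt <- as_pair_tibble(drug_target, c("drug", "target"))
  dd <- as_pair_tibble(drug_disease, c("drug", "disease"))
  td <- as_pair_tibble(target_disease, c("target", "disease"))

  vocab <- build_vocab(
    drugs    = c(dt$drug, dd$drug),
    targets  = c(dt$target, td$target),
    diseases = c(dd$disease, td$disease)
  )

  structure(
    list(drug_target = dt, drug_disease = dd, target_disease = td,
         vocab = vocab),
    class = "pair_tables"
  )
}

as_pair_tibble <- function(x, nms) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) != 2L) {
    abort(sprintf("A pair table needs exactly 2 columns, got %d.", ncol(x)))
  }
  out <- tibble(a = as.character(x[[1]]), b = as.character(x[[2]]))
  names(out) <- nms
  distinct(out)
}

build_vocab <- function(drugs, targets, diseases) {
  one <- function(kind, ids) {
    ids <- sort(unique(ids))
    tibble(kind = kind, id = ids,
           index = seq_along(ids) - 1L)
  }
  bind_rows(one("drug", drugs), one("target", targets),
            one("disease", diseases))
}

# id -> 0-based index lookup within one namespace
vocab_index <- function(vocab, kind, ids) {
  sub <- vocab[vocab$kind == kind, ]
  idx <- sub$index[match(ids, sub$id)]
  if (anyNA(idx)) {
    missing <- unique(ids[is.na(idx)])
    abort(sprintf("Unknown %s identifier(s): %s", kind,
                  paste(head(missing, 5), collapse = ", ")))
  }
  idx
}

vocab_ids <- function(vocab, kind) {
  sub <- vocab[vocab$kind == kind, ]
  sub$id[order(sub$index)]
}

n_of_kind <- function(vocab, kind) sum(vocab$kind == kind)

#' Read the three pairwise relation tables from tab-separated files
#'
#' Each file is a two-column tab-separated edge list; lines starting with
#' `#` and blank lines are ignored. An empty file yields an empty table.
#' Rows are deduplicated and the shared vocabulary is built from the union
#' of observed identifiers in lexicographic order.
#'
#' @param drug_target,drug_disease,target_disease Paths to TSV edge lists.
#' @param quiet Suppress the per-table row-count messages.
#' @return A [pair_tables()] object.
#' @export
read_pair_tables <- function(drug_target, drug_disease, target_disease,
                             quiet = FALSE) {
  dt <- read_edge_tsv(drug_target)
  dd <- read_edge_tsv(drug_disease)
  td <- read_edge_tsv(target_disease)
  out <- pair_tables(dt, dd, td)
  if (!quiet) {
    inform(sprintf(
      "Read %d drug-target, %d drug-disease, %d target-disease pairs (after dedup).",
      nrow(out$drug_target), nrow(out$drug_disease), nrow(out$target_disease)))
  }
  out
}

read_edge_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  kept_lines <- lines[keep]
  line_no <- which(keep)
  if (length(kept_lines) == 0L) {
    return(tibble(a = character(), b = character()))
  }
  parts <- strsplit(kept_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(sprintf("Malformed line %d in %s: expected 2 tab-separated fields, got %d.",
                  line_no[bad[1]], path, lengths(parts)[bad[1]]))
  }
  tibble(a = vapply(parts, `[[`, "", 1L), b = vapply(parts, `[[`, "", 2L))
}

#' Write pair tables as tab-separated edge lists
#'
#' Emits the same dialect [read_pair_tables()] consumes, one file per
#' relation, with a `#`-prefixed header line.
#'
#' @param tables A [pair_tables()] object.
#' @param dir Output directory (created if absent).
#' @return The three file paths, invisibly.
#' @export
write_pair_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "pair_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    drug_target    = file.path(dir, "drug_target.tsv"),
    drug_disease   = file.path(dir, "drug_disease.tsv"),
    target_disease = file.path(dir, "target_disease.tsv")
  )
  for (nm in names(paths)) {
    tab <- tables[[nm]]
    con <- file(paths[[nm]], open = "wb")
    writeLines(c(paste0("# ", paste(names(tab), collapse = "\t")),
                 paste(tab[[1]], tab[[2]], sep = "\t")),
               con, useBytes = TRUE)
    close(con)
  }
  invisible(paths)
}

#' @exportS3Method base::print
print.pair_tables <- function(x, ...) {
  cat("<pair_tables>\n")
  cat(sprintf("  drug-target:    %5d pairs\n", nrow(x$drug_target)))
  cat(sprintf("  drug-disease:   %5d pairs\n", nrow(x$drug_disease)))
  cat(sprintf("  target-disease: %5d pairs\n", nrow(x$target_disease)))
  cat(sprintf("  vocab: %d drugs, %d targets, %d diseases\n",
              n_of_kind(x$vocab, "drug"), n_of_kind(x$vocab, "target"),
              n_of_kind(x$vocab, "disease")))
  invisible(x)
}
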