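# Readers/writers for the plain-text formats the pipeline exchanges:
# guide-count and design TSVs, GCT v1.2 + CLS expression pairs, GMT gene-set
# collections, dose-matrix CSV grids, and survival/prediction/pathway TSVs.

#' Write guide counts as TSV (guide_id, gene_id, one column per sample)
#' @param gc a [guide_counts()] object.
#' @param path output file.
#' @export
write_guide_counts <- function(gc, path) {
  stopifnot(inherits(gc, "guide_counts"))
  df <- data.frame(guide_id = gc$guide_ids, gene_id = gc$gene_ids,
                   gc$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read guide counts written by [write_guide_counts()]
#' @param path TSV file.
#' @export
read_guide_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("guide_id", "gene_id")), drop = FALSE])
  rownames(m) <- df$guide_id
  guide_counts(m, gene_ids = df$gene_id)
}

#' Write / read a screen design table (sample_id, drug, dose, replicate)
#' @param design screen design data.frame.
#' @param path TSV file.
#' @export
write_screen_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_design
#' @export
read_screen_design <- function(path) {
  design <- utils::read.delim(path)
  class(design) <- c("screen_design", "data.frame")
  design
}

#' Write an expression matrix as GCT v1.2 with a matching CLS file
#'
#' GCT v1.2: "#1.2" header, a dimensions line, then Name/Description columns
#' followed by one column per sample. The CLS companion carries the
#' categorical phenotype labels.
#'
#' @param em an [expression_matrix()].
#' @param gct_path,cls_path output files.
#' @export
write_gct_cls <- function(em, gct_path, cls_path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(gct_path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(em$values), ncol(em$values)), con)
  df <- data.frame(Name = em$gene_ids, Description = "na",
                   em$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)

  labs <- unique(em$phenotype)
  cls <- c(sprintf("%d %d 1", length(em$phenotype), length(labs)),
           paste("#", paste(labs, collapse = " ")),
           paste(em$phenotype, collapse = " "))
  writeLines(cls, cls_path)
  invisible(gct_path)
}

#' Read a GCT v1.2 / CLS expression pair
#' @param gct_path,cls_path input files.
#' @return an [expression_matrix()].
#' @export
read_gct_cls <- function(gct_path, cls_path) {
  header <- readLines(gct_path, n = 2)
  if (header[1] != "#1.2") stop("not a GCT v1.2 file: ", gct_path)
  dims <- as.integer(strsplit(header[2], "\t")[[1]])
  df <- utils::read.delim(gct_path, skip = 2, check.names = FALSE)
  if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
    stop("GCT dimensions line disagrees with table body")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$Name
  cls <- readLines(cls_path)
  pheno <- strsplit(trimws(cls[3]), "\\s+")[[1]]
  expression_matrix(m, phenotype = pheno)
}

#' Read / write GMT gene-set collections
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors (members), with per-set
#'   descriptions in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Write / read a dose matrix as a CSV grid with dose headers (nM)
#' @param dm a [dose_matrix()].
#' @param path CSV file.
#' @export
write_dose_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dose_matrix"))
  df <- data.frame(dose_a = dm$dose_a, dm$values, check.names = FALSE)
  names(df)[-1] <- format(dm$dose_b, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_matrix
#' @export
read_dose_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dose_a <- df[[1]]
  dose_b <- as.numeric(names(df)[-1])
  dose_matrix(as.matrix(df[, -1, drop = FALSE]), dose_a = dose_a, dose_b = dose_b)
}

#' Write / read a survival cohort TSV (id, time, event, expression)
#' @param cohort survival cohort data.frame.
#' @param path TSV file.
#' @export
write_survival_cohort <- function(cohort, path) {
  keep <- intersect(c("id", "time", "event", "expression", "group"),
                    names(cohort))
  utils::write.table(cohort[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_cohort
#' @export
read_survival_cohort <- function(path) {
  df <- utils::read.delim(path)
  df$event <- as.logical(df$event)
  class(df) <- c("survival_cohort", "data.frame")
  df
}

#' Read a target-prediction TSV (gene, score)
#'
#' One row per predicted gene with its cumulative weighted context++ score
#' (more negative = stronger predicted repression).
#' @param path TSV file with columns `gene` and `score`.
#' @export
read_target_predictions <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("gene", "score") %in% names(df)))
  df
}

#' Read a pathway map TSV (pathway, designated, members)
#'
#' `members` is a comma-separated gene list; `designated` flags the
#' cancer-associated pathways used by the triage filter.
#' @param path TSV file.
#' @return list with `members` (named list of gene vectors) and `designated`
#'   (character vector of designated pathway ids).
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("pathway", "designated", "members") %in% names(df)))
  members <- lapply(strsplit(df$members, ","), trimws)
  names(members) <- df$pathway
  if (any(lengths(members) == 0)) stop("pathway with empty member list")
  list(members = members,
       designated = df$pathway[as.logical(df$designated)])
}
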