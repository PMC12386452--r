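#' Construct an expression table
#'
#' A gene-by-cell-line abundance matrix (unit-agnostic, e.g. TPM-like)
#' with optional per-line tissue and radiosensitivity annotation. Only
#' ratios between lines are ever consumed downstream, so the absolute
#' scale is irrelevant.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   lines in columns (colnames = line names); all values >= 0, no NA.
#' @param tissue optional named character vector, line -> tissue label.
#' @param label optional named character vector, line -> "RS"/"RR";
#'   missing lines are "unknown".
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, tissue = NULL, label = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  lines <- colnames(values)
  if (is.null(genes) || is.null(lines))
    stop("'values' must have gene rownames and line colnames")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  dup <- unique(lines[duplicated(lines)])
  if (length(dup))
    stop("duplicate cell-line name(s): ", paste(dup, collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', line '%s' (no imputation)",
                 genes[idx[1L]], lines[idx[2L]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at gene '%s', line '%s'",
                 genes[idx[1L]], lines[idx[2L]]))
  }
  tis <- stats::setNames(rep(NA_character_, length(lines)), lines)
  if (!is.null(tissue)) tis[intersect(names(tissue), lines)] <-
      tissue[intersect(names(tissue), lines)]
  lab <- stats::setNames(rep("unknown", length(lines)), lines)
  if (!is.null(label)) lab[intersect(names(label), lines)] <-
      label[intersect(names(label), lines)]
  structure(list(genes = genes, lines = lines, values = values,
                 tissue = tis, label = lab),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d cell lines\n",
              length(x$genes), length(x$lines)))
  invisible(x)
}

#' Read a wide expression matrix from CSV/TSV
#'
#' First column gene symbols, remaining columns one cell line each. An
#' optional metadata sidecar CSV with columns `line,tissue,label` joins
#' tissue and RS/RR annotation.
#'
#' @param path expression file.
#' @param format `"wide_csv"` or `"wide_tsv"`.
#' @param metadata optional path to the metadata CSV.
#' @return An [expression_table()].
#' @export
read_expression <- function(path, format = c("wide_csv", "wide_tsv"),
                            metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (format == "wide_csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >= 1 line column")
  genes <- as.character(df[[1L]])
  line_names <- names(df)[-1L] # before subsetting, which would dedupe
  dup <- unique(line_names[duplicated(line_names)])
  if (length(dup))
    stop("duplicate cell-line name(s): ", paste(dup, collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric abundance values in ", path)
  dimnames(mat) <- list(genes, line_names)
  tissue <- label <- NULL
  if (!is.null(metadata)) {
    md <- read_metadata(metadata)
    tissue <- stats::setNames(md$tissue, md$line)
    label <- stats::setNames(md$label, md$line)
  }
  expression_table(mat, tissue = tissue, label = label)
}

#' Read a `line,tissue,label` metadata CSV
#'
#' @param path CSV with header `line,tissue,label`.
#' @return data.frame with those three character columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "tissue", "label")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(md$line[duplicated(md$line)])
  if (length(dup))
    stop("duplicate line(s) in metadata: ", paste(dup, collapse = ", "))
  md[need]
}

#' Write an expression table (and optional metadata) to disk
#'
#' Inverse of [read_expression()]: wide CSV with a leading `gene` column.
#'
#' @param table an [expression_table()].
#' @param path expression CSV path.
#' @param metadata_path optional path for the `line,tissue,label` sidecar.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path, metadata_path = NULL) {
  df <- data.frame(gene = table$genes, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(line = table$lines,
                     tissue = unname(table$tissue[table$lines]),
                     label = unname(table$label[table$lines]))
    utils::write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Default enzyme-to-gene map
#'
#' Maps each of the six expression-scalable model quantities to the gene
#' family members a transcriptome measures, with the aggregation rule used
#' to collapse family members into one abundance. Catalase and glutathione
#' reductase are single genes; the peroxidase/thioredoxin families are
#' summed. The map is a plain list and can be overridden or loaded from
#' YAML ([read_gene_map()]).
#'
#' @return Named list: for each enzyme, `list(genes = <character>,
#'   rule = "sum"|"mean")`.
#' @export
default_gene_map <- function() {
  list(
    CAT = list(genes = "CAT", rule = "sum"),
    GPX = list(genes = paste0("GPX", 1:4), rule = "sum"),
    GSR = list(genes = "GSR", rule = "sum"),
    TXNRD = list(genes = paste0("TXNRD", 1:3), rule = "sum"),
    PRDX = list(genes = paste0("PRDX", 1:6), rule = "sum"),
    TXN = list(genes = c("TXN", "TXN2"), rule = "sum"))
}

validate_gene_map <- function(map) {
  need <- c("CAT", "GPX", "GSR", "TXNRD", "PRDX", "TXN")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("gene map is missing enzyme(s): ", paste(miss, collapse = ", "))
  for (enz in names(map)) {
    g <- map[[enz]]$genes
    if (length(g) < 1L) stop("enzyme '", enz, "' maps to no genes")
    if (anyDuplicated(g))
      stop("duplicate symbols in gene map for '", enz, "'")
    rule <- map[[enz]]$rule %||% "sum"
    if (!rule %in% c("sum", "mean"))
      stop("aggregation rule for '", enz, "' must be 'sum' or 'mean'")
  }
  invisible(map)
}

#' Read a gene map from YAML
#'
#' Expected layout per enzyme: either a plain list of symbols (rule
#' defaults to sum) or `{genes: [...], rule: sum|mean}`.
#'
#' @param path YAML file.
#' @return A validated gene map list.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  raw <- yaml::read_yaml(path)
  map <- lapply(raw, function(x) {
    if (is.list(x) && !is.null(x$genes))
      list(genes = as.character(x$genes), rule = x$rule %||% "sum")
    else list(genes = as.character(x), rule = "sum")
  })
  validate_gene_map(map)
}

#' Collapse gene-level abundance to enzyme level
#'
#' @param table an [expression_table()].
#' @param map a gene map ([default_gene_map()] layout).
#' @param missing `"error"` (default) stops on a mapped symbol absent from
#'   the table; `"drop"` warns and aggregates over the present symbols.
#' @return Numeric matrix, enzymes x lines.
#' @export
aggregate_genes <- function(table, map = default_gene_map(),
                            missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(table, "expression_table"))
  validate_gene_map(map)
  out <- matrix(NA_real_, nrow = length(map), ncol = length(table$lines),
                dimnames = list(names(map), table$lines))
  for (enz in names(map)) {
    g <- map[[enz]]$genes
    absent <- setdiff(g, table$genes)
    if (length(absent)) {
      if (missing == "error")
        stop("gene(s) for enzyme '", enz, "' not in table: ",
             paste(absent, collapse = ", "))
      warning("dropping absent gene(s) for '", enz, "': ",
              paste(absent, collapse = ", "))
      g <- setdiff(g, absent)
    }
    if (!length(g))
      stop("enzyme '", enz, "' has no resolvable genes in the table")
    sub <- table$values[g, , drop = FALSE]
    rule <- map[[enz]]$rule %||% "sum"
    out[enz, ] <- if (rule == "mean") colMeans(sub) else colSums(sub)
  }
  out
}

#' Expression-ratio scaling of enzyme pools
#'
#' Converts enzyme-level abundance into per-line pools by the ratio to a
#' designated reference line: `factor(line, enzyme) =
#' abundance(line, enzyme) / abundance(reference, enzyme)`. The reference
#' line's factors are exactly 1 and its pools equal the base
#' parameterization. The glutathione pool is a metabolite, not an enzyme,
#' and is never scaled.
#'
#' @param enzyme_expr enzymes x lines matrix from [aggregate_genes()].
#' @param reference_line column name of the reference; its abundance must
#'   be strictly positive for every enzyme.
#' @param base base [enzyme_pools()] assigned to the reference line.
#' @param tissue,label optional named vectors (line -> annotation).
#' @return A `cell_line_profiles` data.frame with columns `line`,
#'   `tissue`, `label` and scaling factors `f_CAT`, `f_GPX`, `f_GSR`,
#'   `f_TXNRD`, `f_PRDX`, `f_TXN`.
#' @export
scale_pools <- function(enzyme_expr, reference_line,
                        base = enzyme_pools(), tissue = NULL,
                        label = NULL) {
  enzymes <- c("CAT", "GPX", "GSR", "TXNRD", "PRDX", "TXN")
  miss <- setdiff(enzymes, rownames(enzyme_expr))
  if (length(miss))
    stop("enzyme abundance matrix lacks row(s): ", paste(miss, collapse = ", "))
  if (!reference_line %in% colnames(enzyme_expr))
    stop("reference line '", reference_line, "' not in the table")
  ref <- enzyme_expr[enzymes, reference_line]
  zero <- enzymes[ref <= 0]
  if (length(zero))
    stop("reference line has zero abundance for enzyme(s): ",
         paste(zero, collapse = ", "))
  lines <- colnames(enzyme_expr)
  fac <- sweep(enzyme_expr[enzymes, , drop = FALSE], 1L, ref, "/")
  fac[, reference_line] <- 1  # exact, not ratio-rounded
  prof <- data.frame(
    line = lines,
    tissue = if (is.null(tissue)) NA_character_ else
      unname(tissue[lines]),
    label = if (is.null(label)) "unknown" else {
      l <- unname(label[lines]); l[is.na(l)] <- "unknown"; l
    },
    t(fac), check.names = FALSE, stringsAsFactors = FALSE)
  names(prof)[4:9] <- paste0("f_", enzymes)
  rownames(prof) <- NULL
  attr(prof, "base_pools") <- base
  class(prof) <- c("cell_line_profiles", "data.frame")
  prof
}

#' Enzyme pools for one profile row
#'
#' Applies a profile's scaling factors to the base pools; `GSH_total` is
#' left at base.
#'
#' @param profile one row of a `cell_line_profiles` data.frame.
#' @param base base [enzyme_pools()]; defaults to the attribute stored on
#'   the profiles.
#' @return An [enzyme_pools()].
#' @export
profile_pools <- function(profile, base = NULL) {
  base <- base %||% attr(profile, "base_pools") %||% enzyme_pools()
  enzyme_pools(
    CAT = base$CAT * profile$f_CAT,
    GPX = base$GPX * profile$f_GPX,
    GSR = base$GSR * profile$f_GSR,
    TXNRD = base$TXNRD * profile$f_TXNRD,
    PRDX_total = base$PRDX_total * profile$f_PRDX,
    TXN_total = base$TXN_total * profile$f_TXN,
    GSH_total = base$GSH_total)
}

#' Write / read cell-line profiles
#'
#' CSV schema: `line,tissue,label,f_CAT,f_GPX,f_GSR,f_TXNRD,f_PRDX,f_TXN`.
#' Factors are written with 15 significant digits so a round-trip
#' reproduces them to at least 12.
#'
#' @param profiles a `cell_line_profiles` data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write); profiles (read).
#' @export
write_profiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  for (j in grep("^f_", names(out))) out[[j]] <- sprintf("%.15g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profiles file not found: ", path)
  prof <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("line", "tissue", "label",
            paste0("f_", c("CAT", "GPX", "GSR", "TXNRD", "PRDX", "TXN")))
  miss <- setdiff(need, names(prof))
  if (length(miss))
    stop("profiles file missing column(s): ", paste(miss, collapse = ", "))
  prof <- prof[need]
  attr(prof, "base_pools") <- enzyme_pools()
  class(prof) <- c("cell_line_profiles", "data.frame")
  prof
}
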