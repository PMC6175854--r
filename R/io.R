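#' Expression matrix container
#'
#' A samples-by-features numeric matrix for one molecular platform of one
#' cancer type. All pipeline code uses the samples-in-rows orientation.
#'
#' @param values Numeric matrix, samples in rows, with complete dimnames.
#' @param platform One of `"protein"`, `"mrna"`, `"mirna"`, `"methylation"`.
#' @param cancer_type Cancer-type code (e.g. `"BRCA"`).
#' @return An object of class `pronet_em`.
#' @export
expression_matrix <- function(values, platform = c("protein", "mrna",
                                                   "mirna", "methylation"),
                              cancer_type = "NA") {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs sample (row) and feature (column) names")
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  dup_f <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  ## features with any missing value are dropped: the modelling steps
  ## assume complete data and no imputation is performed
  bad <- colSums(!is.finite(values)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d feature(s) with missing/non-finite values: %s",
                    sum(bad), paste(utils::head(colnames(values)[bad], 5),
                                    collapse = ", ")))
    values <- values[, !bad, drop = FALSE]
  }
  structure(list(values = values, platform = platform,
                 cancer_type = cancer_type),
            class = "pronet_em")
}

#' @export
print.pronet_em <- function(x, ...) {
  cat(sprintf("<%s expression matrix, %s: %d samples x %d features>\n",
              x$platform, x$cancer_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.pronet_em <- function(x) dim(x$values)

## Accept either a pronet_em or a bare named matrix wherever expression
## data flows in; returns the numeric matrix.
em_values <- function(x) {
  if (inherits(x, "pronet_em")) x$values else as.matrix(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of feature ids and a first column of sample ids.
#'
#' @param path Path to a tab-separated file.
#' @param platform Platform tag (see [expression_matrix()]).
#' @param cancer_type Cancer-type code stored on the object.
#' @return A `pronet_em`.
#' @export
read_expression_matrix <- function(path, platform, cancer_type = "NA") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or malformed matrix file: ", path)
  samples <- raw[[1]]
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  nonnum <- is.na(vals) & !is.na(as.matrix(raw[, -1, drop = FALSE]))
  if (any(nonnum)) {
    idx <- which(nonnum, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at sample '%s', feature '%s'",
                 samples[idx[1]], colnames(vals)[idx[2]]))
  }
  rownames(vals) <- samples
  expression_matrix(vals, platform = platform, cancer_type = cancer_type)
}

#' Write an expression matrix to TSV
#'
#' Canonical format: header `sample_id` + feature ids, one row per sample.
#' Round-trips losslessly with [read_expression_matrix()].
#'
#' @param em A `pronet_em`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(em, path) {
  v <- em_values(em)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway definitions (GMT plus optional sign annotation)
#'
#' Each GMT line is `name <tab> description <tab> member...`. The optional
#' sidecar TSV maps protein features to gene symbols and regulatory signs,
#' with columns `protein`, `gene`, `sign`; members missing from the sidecar
#' default to their own id as gene and sign +1 (positive regulatory
#' components are the common case in the curated pathway lists this models).
#'
#' @param gmt_path Path to the GMT file.
#' @param sign_path Optional path to the protein/gene/sign TSV.
#' @return A named list of pathway definitions, each a list with `name`,
#'   `members` (data.frame `protein`, `gene`, `sign`) and member count `p`.
#' @export
read_pathways <- function(gmt_path, sign_path = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", gmt_path)
  signs <- NULL
  if (!is.null(sign_path)) {
    signs <- utils::read.table(sign_path, header = TRUE, sep = "\t",
                               check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("protein", "gene", "sign") %in% names(signs))) {
      stop("sign file needs columns protein, gene, sign")
    }
    if (!all(signs$sign %in% c(-1, 1))) {
      stop("signs must be +1 or -1")
    }
  }
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with zero members: ", f[1])
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line with zero members: ", f[1])
    if (anyDuplicated(members)) {
      stop("duplicate protein in pathway ", f[1])
    }
    df <- data.frame(protein = members, gene = members,
                     sign = rep(1, length(members)),
                     stringsAsFactors = FALSE)
    if (!is.null(signs)) {
      m <- match(df$protein, signs$protein)
      hit <- !is.na(m)
      df$gene[hit] <- signs$gene[m[hit]]
      df$sign[hit] <- signs$sign[m[hit]]
    }
    list(name = f[1], members = df, p = nrow(df))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Read a protein-protein interaction table
#'
#' Edge-list TSV with columns `protein_a`, `protein_b`, `score`. Raw
#' STRING-style combined scores on the 0-1000 scale are rescaled to [0,1]
#' with `rescale = TRUE`. The table is symmetrised; duplicate or reciprocal
#' rows are collapsed by taking the maximum score; self-pairs are dropped.
#' Pairs absent from the table score 0 on lookup.
#'
#' @param path Path to the TSV.
#' @param rescale Divide scores by 1000 before validation.
#' @return An object of class `pronet_ppi`.
#' @export
read_ppi <- function(path, rescale = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    stop("PPI file needs columns protein_a, protein_b, score")
  }
  ppi_table(df$protein_a, df$protein_b, df$score, rescale = rescale)
}

#' Construct a PPI table from vectors
#'
#' @param a,b Character vectors of interacting proteins.
#' @param score Numeric confidence scores.
#' @param rescale Divide by 1000 (raw STRING combined scores).
#' @return A `pronet_ppi`.
#' @export
ppi_table <- function(a = character(), b = character(), score = numeric(),
                      rescale = FALSE) {
  a <- as.character(a); b <- as.character(b); score <- as.numeric(score)
  stopifnot(length(a) == length(b), length(a) == length(score))
  if (rescale) score <- score / 1000
  if (length(score) && (any(score < 0) || any(score > 1))) {
    stop("PPI scores must lie in [0,1] (after rescaling)")
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  if (length(key)) {
    score <- tapply(score, key, max)
    key <- names(score)
    parts <- strsplit(key, "\r", fixed = TRUE)
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
  }
  structure(list(a = a, b = b, score = as.numeric(score), key = key),
            class = "pronet_ppi")
}

#' @export
print.pronet_ppi <- function(x, ...) {
  cat(sprintf("<PPI table: %d pairs>\n", length(x$score)))
  invisible(x)
}

#' Look up PPI confidence scores
#'
#' Symmetric lookup; unlisted pairs score 0. Vectorised over pairs.
#'
#' @param ppi A `pronet_ppi` (or `NULL`, in which case all scores are 0).
#' @param a,b Protein id vectors (recycled to common length).
#' @return Numeric vector of scores in [0,1].
#' @export
ppi_score <- function(ppi, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  if (is.null(ppi) || !length(ppi$score)) return(numeric(n))
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  m <- match(key, ppi$key)
  out <- ppi$score[m]
  out[is.na(out)] <- 0
  out[a == b] <- 0
  out
}

#' Write a PPI table to TSV
#' @param ppi A `pronet_ppi`.
#' @param path Output path.
#' @export
write_ppi <- function(ppi, path) {
  df <- data.frame(protein_a = ppi$a, protein_b = ppi$b, score = ppi$score)
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an integrated network as JSON
#'
#' Schema: `{nodes:[{id,type}], edges:[{src,dst,kind,pip}]}` with network
#' metadata alongside. Correlative protein edges carry the larger of the two
#' direction-wise inclusion probabilities as `pip`, and both raw values as
#' `pip_fwd`/`pip_rev`.
#'
#' @param network A `pronet_network`.
#' @param path Output path.
#' @export
write_network_json <- function(network, path) {
  nodes <- data.frame(id = network$proteins, type = "protein",
                      stringsAsFactors = FALSE)
  if (nrow(network$upstream_edges)) {
    nodes <- rbind(nodes, data.frame(id = unique(network$upstream_edges$covariate),
                                     type = "upstream", stringsAsFactors = FALSE))
  }
  pe <- network$protein_edges
  ue <- network$upstream_edges
  edges <- rbind(
    if (nrow(pe)) data.frame(src = pe$src, dst = pe$dst, kind = pe$kind,
                             pip = pe$pip, pip_fwd = pe$pip_fwd,
                             pip_rev = pe$pip_rev, stringsAsFactors = FALSE),
    if (nrow(ue)) data.frame(src = ue$covariate, dst = ue$target,
                             kind = "upstream", pip = ue$pip,
                             pip_fwd = ue$pip, pip_rev = NA_real_,
                             stringsAsFactors = FALSE)
  )
  obj <- list(cancer_type = network$cancer_type, pathway = network$pathway,
              nodes = nodes,
              edges = if (is.null(edges)) list() else edges,
              out_degree = as.list(network$C))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an integrated network from JSON
#' @param path Path written by [write_network_json()].
#' @return A `pronet_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  proteins <- nodes$id[nodes$type == "protein"]
  edges <- if (length(obj$edges)) as.data.frame(obj$edges) else
    data.frame(src = character(), dst = character(), kind = character(),
               pip = numeric(), pip_fwd = numeric(), pip_rev = numeric())
  pe <- edges[edges$kind %in% c("regulatory", "correlative"), , drop = FALSE]
  ue <- edges[edges$kind == "upstream", , drop = FALSE]
  C <- unlist(obj$out_degree)
  if (is.null(C)) C <- stats::setNames(numeric(length(proteins)), proteins)
  new_network(cancer_type = obj$cancer_type, pathway = obj$pathway,
              proteins = proteins,
              protein_edges = pe[, c("src", "dst", "kind", "pip",
                                     "pip_fwd", "pip_rev"), drop = FALSE],
              upstream_edges = data.frame(covariate = ue$src, target = ue$dst,
                                          pip = ue$pip,
                                          stringsAsFactors = FALSE),
              C = C[proteins])
}

#' Write a long-format score/probability table
#'
#' Columns `sample`, `unit` (protein or pathway), `quantity`, `value`.
#'
#' @param df A data.frame in wide per-sample form; gathered by this writer.
#' @param path Output path.
#' @param unit_col Name of the column holding the unit id.
#' @export
write_long_tsv <- function(df, path, unit_col = "unit") {
  stopifnot("sample" %in% names(df), unit_col %in% names(df))
  value_cols <- setdiff(names(df), c("sample", unit_col))
  long <- do.call(rbind, lapply(value_cols, function(cn) {
    data.frame(sample = df$sample, unit = df[[unit_col]], quantity = cn,
               value = as.character(df[[cn]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
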