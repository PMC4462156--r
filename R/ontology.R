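#' Ancestors of a hierarchical tree-number code
#'
#' A tree number such as `"C04.557.337"` locates a vocabulary term inside a
#' rooted hierarchy; every proper prefix obtained by truncating the code at a
#' dot identifies an ancestor term. This returns those prefixes ordered from
#' the most general (shortest) to the most specific (longest), excluding the
#' code itself.
#'
#' @param tree_number A single non-empty dot-delimited code string.
#' @return Character vector of proper prefixes, possibly empty for a
#'   top-level code.
#' @examples
#' ancestors_of("C04.557.337")  # "C04", "C04.557"
#' ancestors_of("C04")          # character(0)
#' @export
ancestors_of <- function(tree_number) {
  if (!is.character(tree_number) || length(tree_number) != 1L ||
      is.na(tree_number) || !nzchar(tree_number)) {
    stop("`tree_number` must be a single non-empty string", call. = FALSE)
  }
  parts <- strsplit(tree_number, ".", fixed = TRUE)[[1L]]
  n <- length(parts)
  if (n <= 1L) return(character(0))
  vapply(seq_len(n - 1L), function(k) paste(parts[seq_len(k)], collapse = "."),
         character(1))
}

#' Construct a disease ontology from a term table
#'
#' Builds the in-memory disease vocabulary used throughout the package: a set
#' of terms, each with one or more tree-number codes, plus the parent/child
#' adjacency derived from the codes. The parent of a code is the term owning
#' its nearest *resolvable* proper prefix, so a missing intermediate level in a
#' partial vocabulary does not disconnect deeper terms from their known
#' ancestors.
#'
#' @param terms A data frame with columns `term_id`, `name`, `tree_numbers`
#'   (either a `";"`-separated string or a list column of character vectors).
#' @return An object of class `disease_ontology`.
#' @seealso [parse_descriptor_table()] to read the standard TSV form,
#'   [build_dag()] for per-disease ancestor graphs.
#' @export
disease_ontology <- function(terms) {
  stopifnot(is.data.frame(terms))
  needed <- c("term_id", "name", "tree_numbers")
  if (!all(needed %in% names(terms))) {
    stop("`terms` needs columns term_id, name, tree_numbers", call. = FALSE)
  }
  term_id <- as.character(terms$term_id)
  if (anyDuplicated(term_id)) {
    stop("duplicate term_id: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "),
         call. = FALSE)
  }
  tn <- terms$tree_numbers
  if (!is.list(tn)) {
    tn <- lapply(as.character(tn), function(x) {
      codes <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
      codes[nzchar(codes)]
    })
  }
  empty <- lengths(tn) == 0L
  if (any(empty)) {
    warning(sum(empty), " term(s) without tree numbers dropped: ",
            paste(term_id[empty], collapse = ", "), call. = FALSE)
    terms <- terms[!empty, , drop = FALSE]
    term_id <- term_id[!empty]
    tn <- tn[!empty]
  }
  if (nrow(terms) == 0L) stop("ontology has no usable terms", call. = FALSE)

  all_codes <- unlist(tn, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop("tree number assigned to more than one term: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "),
         call. = FALSE)
  }
  code2term <- stats::setNames(rep(term_id, lengths(tn)), all_codes)

  # parent via the nearest resolvable proper prefix of each code
  parents <- stats::setNames(vector("list", length(term_id)), term_id)
  unresolved <- character(0)
  for (i in seq_along(term_id)) {
    p <- character(0)
    for (code in tn[[i]]) {
      anc <- rev(ancestors_of(code))       # most specific first
      hit <- anc[anc %in% names(code2term)]
      if (length(anc) > 0L && length(hit) < length(anc)) {
        unresolved <- c(unresolved, setdiff(anc, hit))
      }
      if (length(hit) > 0L) p <- c(p, code2term[[hit[1L]]])
    }
    parents[[i]] <- unique(p)
  }
  if (length(unresolved) > 0L) {
    message("skipping ", length(unique(unresolved)),
            " unresolvable tree-number prefix(es): ",
            paste(sort(unique(unresolved)), collapse = ", "))
  }

  structure(
    list(term_id = term_id,
         name = stats::setNames(as.character(terms$name), term_id),
         tree_numbers = stats::setNames(tn, term_id),
         code2term = code2term,
         parents = parents),
    class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("disease_ontology:", length(x$term_id), "terms,",
      length(x$code2term), "tree numbers\n")
  invisible(x)
}

#' Read a disease descriptor table
#'
#' Reads a tab-delimited file with header `term_id`, `name`, `tree_numbers`,
#' where `tree_numbers` holds one or more `";"`-separated hierarchical codes.
#' Rows whose code list is empty are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A [disease_ontology()].
#' @export
parse_descriptor_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty descriptor table: ", path, call. = FALSE)
  # strsplit() drops trailing empty fields, but a trailing tab is a legitimate
  # empty final column in TSV, so pad each row back to its tab count + 1
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_tabs <- lengths(gregexpr("\t", lines, fixed = TRUE))
  n_tabs[!grepl("\t", lines, fixed = TRUE)] <- 0L
  fields <- mapply(function(f, k) c(f, rep("", k + 1L - length(f))),
                   fields, n_tabs, SIMPLIFY = FALSE)
  header <- fields[[1L]]
  if (length(header) != 3L ||
      !identical(tolower(trimws(header)), c("term_id", "name", "tree_numbers"))) {
    stop("descriptor table must have header: term_id, name, tree_numbers",
         call. = FALSE)
  }
  body <- fields[-1L]
  keep <- !vapply(body, function(f) length(f) == 1L && !nzchar(f[1L]), logical(1))
  body <- body[keep]
  bad <- which(lengths(body) != 3L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L] + 1L, ": expected 3 tab-separated ",
         "columns, found ", length(body[[bad[1L]]]), call. = FALSE)
  }
  m <- do.call(rbind, body)
  disease_ontology(data.frame(term_id = m[, 1L], name = m[, 2L],
                              tree_numbers = m[, 3L],
                              stringsAsFactors = FALSE))
}

#' Build the ancestor DAG of a disease
#'
#' For a disease `A` the graph `DAG(A) = (D(A), E(A))` contains `A` itself and
#' every ancestor term reachable through the prefix chains of all of `A`'s
#' tree numbers (union across codes), with directed edges from parent to
#' child. The `layer` of a node is the length of the shortest directed path
#' from that node down to `A`; the disease itself sits in layer 0.
#'
#' @param ontology A [disease_ontology()].
#' @param disease A term id present in the ontology.
#' @return An object of class `disease_dag` with elements `disease`, `nodes`,
#'   `edges` (two-column character matrix, parent then child), and `layer`
#'   (named integer vector).
#' @export
build_dag <- function(ontology, disease) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!disease %in% ontology$term_id) {
    stop("unknown disease term: ", disease, call. = FALSE)
  }
  nodes <- disease
  frontier <- disease
  while (length(frontier) > 0L) {
    next_up <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    next_up <- setdiff(next_up, nodes)
    nodes <- c(nodes, next_up)
    frontier <- next_up
  }
  # edges: ontology adjacency restricted to the node set
  edges <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  for (child in nodes) {
    for (parent in intersect(ontology$parents[[child]], nodes)) {
      edges <- rbind(edges, c(parent, child))
    }
  }
  # layer: BFS upward from the disease along child -> parent links
  layer <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  layer[disease] <- 0L
  frontier <- disease
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    up <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    up <- up[up %in% nodes & is.na(layer[up])]
    layer[up] <- d
    frontier <- up
  }
  structure(list(disease = disease, nodes = nodes, edges = edges,
                 layer = layer),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease_dag for", x$disease, ":", length(x$nodes), "nodes,",
      nrow(x$edges), "edges, depth", max(x$layer), "\n")
  invisible(x)
}

#' Construct an association table
#'
#' Wraps a binary lncRNA-by-disease matrix (rows lncRNAs, columns diseases)
#' with validated identifiers.
#'
#' @param matrix A binary matrix with lncRNA row names and disease term-id
#'   column names.
#' @return Object of class `association_table` with fields `matrix`,
#'   `lncrna_ids`, `disease_ids`.
#' @export
association_table <- function(matrix) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("association matrix needs lncRNA row names and disease column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate identifiers in association matrix", call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) {
    stop("association matrix entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(m) <- "double"
  structure(list(matrix = m, lncrna_ids = rownames(m),
                 disease_ids = colnames(m)),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("association_table:", length(x$lncrna_ids), "lncRNAs x",
      length(x$disease_ids), "diseases,", sum(x$matrix), "associations\n")
  invisible(x)
}

#' Map raw lncRNA-disease pairs onto the vocabulary
#'
#' Disease names from association databases rarely match vocabulary term ids
#' directly; this maps each (lncRNA, disease name) record through a
#' name-to-term table, merges names that share a descriptor, collapses
#' duplicate records, and drops names with no mapping. Names are lower-cased
#' and trimmed before lookup.
#'
#' @param raw_pairs Data frame with columns `lncrna` and `disease`
#'   (free-text disease names).
#' @param name_map Named character vector (or 2-column data frame
#'   `disease_name`, `term_id`) mapping disease names to term ids.
#' @param ontology A [disease_ontology()]; pairs whose mapped term is absent
#'   from it are dropped alongside unmapped names.
#' @return An [association_table()].
#' @export
map_associations <- function(raw_pairs, name_map, ontology) {
  stopifnot(is.data.frame(raw_pairs),
            all(c("lncrna", "disease") %in% names(raw_pairs)),
            inherits(ontology, "disease_ontology"))
  if (is.data.frame(name_map)) {
    name_map <- stats::setNames(as.character(name_map$term_id),
                                as.character(name_map$disease_name))
  }
  names(name_map) <- tolower(trimws(names(name_map)))
  dname <- tolower(trimws(as.character(raw_pairs$disease)))
  term <- unname(name_map[dname])
  ok <- !is.na(term) & term %in% ontology$term_id
  if (any(!ok)) {
    message("dropped ", sum(!ok),
            " association record(s) with unmapped disease name(s)")
  }
  lnc <- as.character(raw_pairs$lncrna)[ok]
  term <- term[ok]
  if (length(lnc) == 0L) {
    stop("no associations remain after disease-name mapping", call. = FALSE)
  }
  keep <- !duplicated(paste(lnc, term, sep = "\r"))
  lnc <- lnc[keep]
  term <- term[keep]
  m <- matrix(0, nrow = length(unique(lnc)), ncol = length(unique(term)),
              dimnames = list(sort(unique(lnc)), sort(unique(term))))
  m[cbind(lnc, term)] <- 1
  association_table(m)
}
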