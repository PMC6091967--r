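## Readers/writers for the external formats the pipeline touches:
## FASTA, FASTQ (phred+33), newick, jplace (JSON) and TSV tables.
## Sequence records travel as plain data frames (one row per read) with
## columns id, sample_id, bases and a list column of integer qualities.

#' Construct a set of sequence records
#'
#' @param id Character vector of unique record ids.
#' @param bases Character vector of sequences over A/C/G/T/N (other
#'   letters are mapped to N with a warning).
#' @param sample_id Sample of origin (recycled).
#' @param qualities Optional list of integer phred scores, one vector per
#'   record, each the same length as its sequence.
#' @return A `data.frame` with columns `id`, `sample_id`, `bases`,
#'   `qualities` (list column, entries may be NULL).
#' @export
sequence_records <- function(id, bases, sample_id = NA_character_,
                             qualities = NULL) {
  id <- as.character(id)
  bases <- normalize_bases(as.character(bases))
  if (length(id) != length(bases)) {
    stop("`id` and `bases` must have the same length")
  }
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (any(nchar(bases) < 1L)) stop("sequences must be non-empty")
  if (is.null(qualities)) {
    qualities <- vector("list", length(id))
  } else {
    stopifnot(length(qualities) == length(id))
    ok <- vapply(seq_along(qualities), function(i) {
      is.null(qualities[[i]]) || length(qualities[[i]]) == nchar(bases[[i]])
    }, logical(1))
    if (!all(ok)) stop("qualities must align 1:1 with bases")
  }
  out <- data.frame(id = id,
                    sample_id = rep_len(as.character(sample_id), length(id)),
                    bases = bases, stringsAsFactors = FALSE)
  out$qualities <- qualities
  out
}

## Uppercase and restrict to the A/C/G/T/N alphabet; anything else
## (ambiguity codes, stray characters) becomes missing data (N).
normalize_bases <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
    warning(sprintf("%d sequence(s) contained characters outside {A,C,G,T,N}; mapped to N",
                    sum(bad)), call. = FALSE)
  }
  x
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param sample_id Sample id attached to every record.
#' @return Sequence records as from [sequence_records()] (no qualities).
#' @export
read_fasta <- function(path, sample_id = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(sequence_records(character(), character(), sample_id))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop(sprintf("malformed FASTA in '%s': line 1 is not a '>' header", path))
  }
  idx <- cumsum(is_hdr)
  ## the whole header line is the id: reference ids are species labels
  ## that may contain spaces
  ids <- trimws(sub("^>\\s*", "", lines[is_hdr]))
  if (any(!nzchar(ids))) {
    bad <- which(is_hdr)[!nzchar(ids)][1L]
    stop(sprintf("malformed FASTA in '%s': empty header at line %d", path, bad))
  }
  seqs <- vapply(split(lines[!is_hdr], idx[!is_hdr]), paste0,
                 character(1), collapse = "")
  full <- character(length(ids))
  full[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(full))) {
    bad <- which(is_hdr)[which(!nzchar(full))[1L]]
    stop(sprintf("malformed FASTA in '%s': empty sequence for header at line %d",
                 path, bad))
  }
  sequence_records(ids, full, sample_id)
}

#' Write sequence records to FASTA
#'
#' Headers may carry `;sample=S;size=N` style annotations supplied via
#' `annotations` (a character vector recycled along records).
#'
#' @param records Sequence records (see [sequence_records()]).
#' @param path Output path.
#' @param annotations Optional per-record header suffix.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, annotations = NULL) {
  hdr <- paste0(">", records$id,
                if (is.null(annotations)) "" else rep_len(annotations, nrow(records)))
  writeLines(as.vector(rbind(hdr, records$bases)), path)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @inheritParams read_fasta
#' @return Sequence records with decoded integer qualities.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(sequence_records(character(), character(), sample_id))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ in '%s': %d lines is not a multiple of 4",
                 path, length(lines)))
  }
  n <- length(lines) %/% 4L
  ids <- sub("^@", "", lines[seq(1L, by = 4L, length.out = n)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    i <- which(mism)[1L]
    stop(sprintf("malformed FASTQ in '%s': sequence/quality length mismatch at record %d (line %d)",
                 path, i, 4L * i - 2L))
  }
  qlist <- lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
  sequence_records(ids, seqs, sample_id, qualities = qlist)
}

#' Write sequence records to FASTQ (phred+33)
#'
#' Records without qualities are written with a constant phred 40 ('I').
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- vapply(seq_len(nrow(records)), function(i) {
    q <- records$qualities[[i]]
    if (is.null(q)) strrep("I", nchar(records$bases[[i]]))
    else rawToChar(as.raw(q + 33L))
  }, character(1))
  writeLines(as.vector(rbind(paste0("@", records$id), records$bases,
                             "+", qual)), path)
  invisible(path)
}

#' Read a newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: accepts either a
#' newick string or a file path, requires branch lengths, and rejects
#' duplicate leaf labels.
#'
#' @param text A newick string, or the path of a file containing one.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("newick parse error: malformed tree text")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("newick parse error: duplicate leaf labels: ",
         paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("newick parse error: tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("newick parse error: negative branch lengths")
  }
  tree
}

#' Write a tree as newick text
#'
#' @param tree An [ape::phylo] tree.
#' @param digits Significant digits for branch lengths.
#' @return A newick string (terminated by ';').
#' @export
write_newick <- function(tree, digits = 12L) {
  old <- options(digits = digits)
  on.exit(options(old))
  ape::write.tree(tree)
}

jplace_required_toplevel <- c("tree", "placements", "fields", "version")
jplace_required_fields <- c("edge_num", "likelihood", "like_weight_ratio",
                            "distal_length", "pendant_length")

#' Read a jplace placement document
#'
#' Parses the jplace JSON dialect (version 3): a newick tree with `{N}`
#' edge numbers, a `fields` vector naming the placement columns (any
#' order accepted), and one entry per query. Placement columns are
#' returned in the canonical order regardless of the file's field order.
#'
#' @param path Path to a jplace file.
#' @return An object of class `jplace`: a list with `tree` (phylo with
#'   an `edge.num` vector parallel to the edge matrix), `placements`
#'   (named list; each element has `name`, `multiplicity` and a
#'   data.frame `p`), `fields`, `version` and `metadata`.
#' @export
read_jplace <- function(path) {
  stopifnot(file.exists(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  missing_top <- setdiff(jplace_required_toplevel, names(doc))
  if (length(missing_top)) {
    stop("jplace format error: missing required field(s): ",
         paste(missing_top, collapse = ", "))
  }
  fields <- unlist(doc$fields)
  missing_f <- setdiff(jplace_required_fields, fields)
  if (length(missing_f)) {
    stop("jplace format error: 'fields' omits: ",
         paste(missing_f, collapse = ", "))
  }
  tree <- parse_jplace_tree(doc$tree)
  placements <- lapply(doc$placements, function(pl) {
    if (!is.null(pl$nm)) {
      name <- as.character(pl$nm[[1]][[1]])
      mult <- as.numeric(pl$nm[[1]][[2]])
    } else {
      name <- as.character(pl$n[[1]])
      mult <- 1
    }
    p <- do.call(rbind, lapply(pl$p, function(row) {
      stats::setNames(as.data.frame(lapply(row, as.numeric)), fields)
    }))
    p <- p[jplace_required_fields]
    p$edge_num <- as.integer(p$edge_num)
    bad <- setdiff(p$edge_num, tree$edge.num)
    if (length(bad)) {
      stop("jplace format error: placement references unknown edge number(s): ",
           paste(bad, collapse = ", "))
    }
    list(name = name, multiplicity = mult, p = p)
  })
  names(placements) <- vapply(placements, `[[`, character(1), "name")
  structure(list(tree = tree, placements = placements,
                 fields = jplace_required_fields,
                 version = as.integer(doc$version),
                 metadata = doc$metadata),
            class = "jplace")
}

## The jplace tree dialect attaches "{N}" after the branch length of the
## edge above each node. We fold each tag into the node's label
## ("name:0.1{3}" -> "name##3:0.1"), delegate the newick itself to ape,
## then recover the per-edge numbers from the labels.
parse_jplace_tree <- function(text) {
  tagged <- gsub("([^,():{}]*):([^,(){}]+)\\{([0-9]+)\\}", "\\1##\\3:\\2", text)
  tree <- ape::read.tree(text = tagged)
  if (is.null(tree)) stop("jplace format error: unparseable tree string")
  ntip <- length(tree$tip.label)
  node_num <- rep(NA_integer_, ntip + tree$Nnode)
  split_tag <- function(lab) {
    m <- regmatches(lab, regexec("^(.*)##([0-9]+)$", lab))[[1]]
    if (length(m) == 3L) list(label = m[2], num = as.integer(m[3]))
    else list(label = lab, num = NA_integer_)
  }
  for (i in seq_len(ntip)) {
    st <- split_tag(tree$tip.label[i])
    tree$tip.label[i] <- st$label
    node_num[i] <- st$num
  }
  if (!is.null(tree$node.label)) {
    for (j in seq_len(tree$Nnode)) {
      st <- split_tag(tree$node.label[j])
      tree$node.label[j] <- st$label
      node_num[ntip + j] <- st$num
    }
  }
  tree$edge.num <- node_num[tree$edge[, 2L]]
  if (anyNA(tree$edge.num)) {
    stop("jplace format error: tree edges lack {N} edge numbers")
  }
  tree
}

## Serialize a phylo tree (carrying tree$edge.num) into the jplace
## newick dialect, depth-first from the root. Spaces in labels become
## underscores (the usual newick convention).
jplace_tree_string <- function(tree, digits = 12L) {
  ntip <- length(tree$tip.label)
  tree$tip.label <- gsub(" ", "_", tree$tip.label, fixed = TRUE)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node) {
    kid_edges <- children[[as.character(node)]]
    inner <- if (is.null(kid_edges)) "" else {
      paste0("(", paste(vapply(kid_edges, function(e) {
        child <- tree$edge[e, 2L]
        paste0(rec(child), ":", fmt(tree$edge.length[e]),
               "{", tree$edge.num[e], "}")
      }, character(1)), collapse = ","), ")")
    }
    label <- if (node <= ntip) tree$tip.label[node] else ""
    paste0(inner, label)
  }
  root <- ntip + 1L
  paste0(rec(root), ";")
}

#' Write a jplace placement document
#'
#' Emits jplace version 3 with the canonical field order
#' `edge_num, likelihood, like_weight_ratio, distal_length,
#' pendant_length`.
#'
#' @param doc A `jplace` object (see [read_jplace()] / [build_jplace()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(doc, path) {
  stopifnot(inherits(doc, "jplace"))
  placements <- lapply(doc$placements, function(pl) {
    list(p = lapply(seq_len(nrow(pl$p)), function(i) {
      row <- pl$p[i, jplace_required_fields]
      list(as.integer(row$edge_num), row$likelihood, row$like_weight_ratio,
           row$distal_length, row$pendant_length)
    }),
    nm = list(list(pl$name, pl$multiplicity)))
  })
  out <- list(version = 3L,
              tree = jplace_tree_string(doc$tree),
              placements = unname(placements),
              fields = as.list(jplace_required_fields),
              metadata = if (is.null(doc$metadata)) {
                list(invocation = "treebard")
              } else doc$metadata)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a TSV table against a schema
#'
#' Header-driven: columns are located by name, so column order is free.
#' Schema columns are type-converted; unknown columns are preserved as
#' character.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @return A `data.frame` with schema columns first, in schema order.
#' @export
read_tabular <- function(path, schema) {
  stopifnot(file.exists(path), is.character(schema), !is.null(names(schema)))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop(sprintf("table format error in '%s': missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
      character = as.character(df[[nm]]),
      integer = as.integer(df[[nm]]),
      double = as.numeric(df[[nm]]),
      logical = tolower(df[[nm]]) %in% c("true", "yes", "1", "t"),
      stop("unknown schema type: ", schema[[nm]])
    )
  }
  df[c(names(schema), setdiff(names(df), names(schema)))]
}
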