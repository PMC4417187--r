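#' Annotated mitochondrial genome container
#'
#' An `mt_genome` holds the deposited heavy-strand sequence of a (usually
#' circular) mitochondrial genome together with typed, stranded features.
#' Feature types are restricted to the four classes the downstream analyses
#' use: `dloop` (control region), `rRNA`, `tRNA` and `CDS`. Coordinates are
#' 1-based inclusive as in GenBank files; a feature on a circular molecule
#' may wrap the origin, in which case `end < start`.
#'
#' @param id record identifier
#' @param sequence DNA string over A,C,G,T (upper case enforced)
#' @param features data.frame with columns `name`, `ftype`, `start`, `end`,
#'   `strand` ("+" or "-")
#' @param circular logical, is the molecule circular
#' @param genetic_code NCBI genetic-code id used for its CDS (default "2",
#'   vertebrate mitochondrial)
#' @return object of class `mt_genome`
#' @export
mt_genome <- function(id, sequence, features, circular = TRUE,
                      genetic_code = "2") {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("empty sequence")
  }
  if (grepl("[^ACGT]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
    stop("sequence contains non-ACGT characters: ", paste(bad, collapse = ","))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "ftype", "start", "end", "strand")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features <- features[need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  g <- structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features, genetic_code = genetic_code),
    class = "mt_genome"
  )
  validate_mt_genome(g)
}

validate_mt_genome <- function(g) {
  n <- genome_length(g)
  f <- g$features
  if (nrow(f)) {
    if (!all(f$ftype %in% c("dloop", "rRNA", "tRNA", "CDS"))) {
      stop("unknown feature type(s): ",
           paste(setdiff(unique(f$ftype), c("dloop", "rRNA", "tRNA", "CDS")),
                 collapse = ", "))
    }
    if (!all(f$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    if (any(f$start < 1L) || any(f$end < 1L) ||
        any(f$start > n) || any(f$end > n)) {
      stop("feature outside sequence bounds [1, ", n, "]")
    }
    wraps <- f$end < f$start
    if (any(wraps) && !g$circular) {
      stop("wrap-around feature on a linear molecule: ",
           paste(f$name[wraps], collapse = ", "))
    }
    if (sum(f$ftype == "dloop") > 1L) {
      stop("more than one D-loop feature")
    }
  }
  g
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %d bp, %s, %d features (%d CDS, %d tRNA, %d rRNA, %d D-loop)\n",
              x$id, genome_length(x),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              sum(x$features$ftype == "CDS"),
              sum(x$features$ftype == "tRNA"),
              sum(x$features$ftype == "rRNA"),
              sum(x$features$ftype == "dloop")))
  invisible(x)
}

#' @export
#' @rdname mt_genome
genome_length <- function(g) nchar(g$sequence)

# 1-based position vector covered by a (possibly wrapping) feature, in
# 5'->3' heavy-strand order
feature_positions <- function(g, start, end) {
  n <- genome_length(g)
  if (end >= start) {
    start:end
  } else {
    if (!g$circular) stop("wrap-around interval on linear molecule")
    c(start:n, 1:end)
  }
}

# heavy-strand subsequence of a feature; coding-strand if coding_strand = TRUE
feature_sequence <- function(g, i, coding_strand = TRUE) {
  f <- g$features[i, ]
  pos <- feature_positions(g, f$start, f$end)
  s <- paste(strsplit(g$sequence, "")[[1]][pos], collapse = "")
  if (coding_strand && f$strand == "-") revcomp(s) else s
}

# faster substring extraction for non-wrapping intervals
substr_seq <- function(seq, start, end) substr(seq, start, end)

#' Parse a GenBank flat-file record into an `mt_genome`
#'
#' A deliberately small reader for single-record GenBank flat files as
#' deposited for mitochondrial genomes: the LOCUS line (length and
#' circular/linear topology), the FEATURES table and the ORIGIN sequence
#' block. Feature keys `CDS`, `tRNA` and `rRNA` map to their classes;
#' `D-loop` — or any key/qualifier mentioning "control region" — maps to
#' `dloop`. `source` and `gene` keys are skipped silently (they duplicate
#' the typed features); any other key is ignored with a warning. Locations
#' of the forms `a..b`, `complement(a..b)` and an origin-spanning
#' `join(a..N,1..b)` are understood; other compound locations are rejected
#' (no splicing in mitochondria).
#'
#' @param x path to a GenBank file, or a character vector of its lines
#' @param genetic_code NCBI code id recorded on the genome (default "2")
#' @return `mt_genome`
#' @export
parse_genbank <- function(x, genetic_code = "2") {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L) stop("parse error: expected exactly one LOCUS line")
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  id <- toks[2]
  circular <- any(grepl("^circular$", toks, ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L) stop("parse error: missing ORIGIN sequence block")
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori][1] else length(lines) + 1L
  seq_lines <- if (endrec - 1L >= ori + 1L) {
    lines[(ori + 1L):(endrec - 1L)]
  } else {
    character(0)
  }
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("parse error: empty ORIGIN block")

  fstart <- grep("^FEATURES", lines)
  features <- data.frame(name = character(0), ftype = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
  if (length(fstart) == 1L && fstart < ori) {
    flines <- lines[(fstart + 1L):(ori - 1L)]
    features <- parse_feature_table(flines)
  }
  mt_genome(id, sequence, features, circular = circular,
            genetic_code = genetic_code)
}

parse_feature_table <- function(flines) {
  # a new feature starts with a key in columns 6..20 (i.e. 5 leading spaces)
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  recs <- list()
  skipped <- character(0)
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
    block <- flines[from:to]
    head <- trimws(block[1])
    key <- sub("[[:space:]].*$", "", head)
    loc <- trimws(sub("^\\S+[[:space:]]+", "", head))
    # continuation lines belonging to the location (before any qualifier)
    quals_at <- grep("^[[:space:]]*/", block)
    loc_end <- if (length(quals_at)) quals_at[1] - 1L else length(block)
    if (loc_end > 1L) {
      loc <- paste0(loc, paste(trimws(block[2:loc_end]), collapse = ""))
    }
    qual_text <- paste(block, collapse = " ")
    ftype <- switch(key,
      "CDS" = "CDS", "tRNA" = "tRNA", "rRNA" = "rRNA",
      "D-loop" = "dloop", "D_loop" = "dloop",
      NA_character_)
    if (is.na(ftype) && grepl("control region", qual_text, ignore.case = TRUE)) {
      ftype <- "dloop"
    }
    if (is.na(ftype)) {
      if (!key %in% c("source", "gene")) skipped <- c(skipped, key)
      next
    }
    pl <- parse_location(loc)
    nm <- feature_name(block, key, ftype)
    recs[[length(recs) + 1L]] <- data.frame(
      name = nm, ftype = ftype, start = pl$start, end = pl$end,
      strand = pl$strand, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("ignored feature key(s): ", paste(unique(skipped), collapse = ", "))
  }
  if (length(recs)) do.call(rbind, recs) else
    data.frame(name = character(0), ftype = character(0), start = integer(0),
               end = integer(0), strand = character(0), stringsAsFactors = FALSE)
}

parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L) {
      stop("unsupported compound location: ", loc)
    }
    a <- parse_simple_span(parts[1])
    b <- parse_simple_span(parts[2])
    if (b$start != 1L) {
      stop("unsupported compound location (not origin-spanning): ", loc)
    }
    return(list(start = a$start, end = b$end, strand = strand))
  }
  sp <- parse_simple_span(loc)
  list(start = sp$start, end = sp$end, strand = strand)
}

parse_simple_span <- function(s) {
  s <- trimws(s)
  if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
    ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
    list(start = ab[1], end = ab[2])
  } else if (grepl("^[0-9]+$", s)) {
    list(start = as.integer(s), end = as.integer(s))
  } else {
    stop("cannot parse location span: ", s)
  }
}

feature_name <- function(block, key, ftype) {
  for (q in c("gene", "product", "note")) {
    hit <- grep(sprintf("/%s=", q), block, value = TRUE)
    if (length(hit)) {
      v <- sub(sprintf('^.*?/%s="?([^"]*)"?.*$', q), "\\1", hit[1])
      if (nzchar(v)) return(v)
    }
  }
  if (ftype == "dloop") "D-loop" else key
}

#' Serialize an `mt_genome` back to GenBank flat-file text
#'
#' Writes the minimal record `parse_genbank()` reads, preserving sequence
#' and feature coordinates exactly (round-trip safe).
#'
#' @param g `mt_genome`
#' @param path optional file path; if omitted, the lines are returned
#' @return character vector of lines, invisibly when written to `path`
#' @export
write_genbank <- function(g, path = NULL) {
  n <- genome_length(g)
  lines <- sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                   g$id, n, if (g$circular) "circular" else "linear")
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  lines <- c(lines, sprintf("     source          1..%d", n))
  f <- g$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$ftype[i], dloop = "D-loop", f$ftype[i])
    span <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$end[i] < f$start[i]) {
      span <- sprintf("join(%d..%d,1..%d)", f$start[i], n, f$end[i])
    }
    if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
    lines <- c(lines, sprintf("     %-15s %s", key, span),
               sprintf('                     /gene="%s"', f$name[i]))
  }
  lines <- c(lines, "ORIGIN")
  chars <- strsplit(tolower(g$sequence), "")[[1]]
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    block <- chars[s:min(s + 59L, n)]
    groups <- split(block, (seq_along(block) - 1L) %/% 10L)
    lines <- c(lines, sprintf("%9d %s", s,
                              paste(vapply(groups, paste, "", collapse = ""),
                                    collapse = " ")))
  }
  lines <- c(lines, "//")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Non-D-loop arc of a genome
#'
#' Excises the D-loop (control region) from a circular genome and returns
#' the remaining arc as a single linear string, starting at the base
#' immediately 3' of the D-loop. Repeats are never scanned across the cut:
#' the excised molecule is treated as strictly linear. A genome without a
#' D-loop is returned unchanged.
#'
#' @param g `mt_genome`
#' @return DNA string
#' @export
non_dloop_sequence <- function(g) {
  arc <- non_dloop_arc(g)
  paste(strsplit(g$sequence, "")[[1]][arc$positions], collapse = "")
}

# positions (1-based, heavy strand, in arc order) of the non-D-loop arc,
# plus a lookup from genome position to arc index
non_dloop_arc <- function(g) {
  n <- genome_length(g)
  d <- which(g$features$ftype == "dloop")
  if (length(d) > 1L) stop("more than one D-loop feature")
  if (length(d) == 0L) {
    pos <- seq_len(n)
  } else {
    f <- g$features[d, ]
    dpos <- feature_positions(g, f$start, f$end)
    if (g$circular) {
      # arc runs 5'->3' from the base just after the D-loop end around to
      # the base just before its start
      after <- if (f$end == n) 1L else f$end + 1L
      all_order <- c(seq(after, n), if (after > 1L) seq(1L, after - 1L))
      pos <- all_order[!(all_order %in% dpos)]
    } else {
      pos <- setdiff(seq_len(n), dpos)
    }
  }
  lookup <- integer(n)
  lookup[pos] <- seq_along(pos)
  list(positions = pos, lookup = lookup)
}

#' Concatenated protein-coding sequence
#'
#' Concatenates all CDS features in genome order on their coding strands.
#' With `omit_terminal_codons = TRUE` (the convention for codon-usage work)
#' the initiation codon and the terminal stop of every gene are dropped;
#' stops annotated as incomplete ("T" or "TA", completed by
#' polyadenylation, common in mammalian mtDNA) count as the stop and are
#' dropped with it. Overlapping CDS (e.g. ATP8/ATP6) are concatenated
#' independently, duplicating the overlapped bases; overlaps are reported
#' via a message.
#'
#' @param g `mt_genome`
#' @param omit_terminal_codons drop initiation and stop codons per gene
#' @return object of class `coding_sequence`: list with `genome_id`,
#'   `nucleotides` (in-frame DNA string), `genes` (data.frame of gene name
#'   and 1-based start offset in the concatenation)
#' @export
concatenated_cds <- function(g, omit_terminal_codons = TRUE) {
  cds <- which(g$features$ftype == "CDS")
  stops <- stop_codons(g$genetic_code)
  parts <- character(0)
  names_out <- character(0)
  if (length(cds) >= 2L) {
    f <- g$features[cds, ]
    iv <- f[order(f$start), ]
    ov <- which(iv$start[-1] <= iv$end[-nrow(iv)] & iv$end[-nrow(iv)] >= iv$start[-1])
    if (length(ov)) {
      message("overlapping CDS: ",
              paste(sprintf("%s/%s", iv$name[ov], iv$name[ov + 1L]), collapse = ", "))
    }
  }
  for (i in cds) {
    nm <- g$features$name[i]
    s <- feature_sequence(g, i, coding_strand = TRUE)
    if (omit_terminal_codons) {
      if (nchar(s) < 9L) {
        stop("CDS too short to trim terminal codons: ", nm)
      }
      s <- substr(s, 4L, nchar(s))          # drop initiation codon
      rem <- nchar(s) %% 3L
      if (rem > 0L) {
        s <- substr(s, 1L, nchar(s) - rem)  # incomplete stop (T / TA)
      } else {
        last <- substr(s, nchar(s) - 2L, nchar(s))
        if (!last %in% stops) {
          warning("terminal codon of ", nm, " is not a stop (", last,
                  "); dropped as annotated terminator")
        }
        s <- substr(s, 1L, nchar(s) - 3L)
      }
    } else {
      if (nchar(s) %% 3L != 0L) {
        stop("CDS length not a multiple of 3 for gene: ", nm)
      }
    }
    parts <- c(parts, s)
    names_out <- c(names_out, nm)
  }
  nt <- paste(parts, collapse = "")
  offs <- if (length(parts)) cumsum(c(1L, head(nchar(parts), -1L))) else integer(0)
  structure(
    list(genome_id = g$id, nucleotides = nt,
         genes = data.frame(gene = names_out, start = offs,
                            stringsAsFactors = FALSE)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons) from %d genes\n",
              x$genome_id, nchar(x$nucleotides), nchar(x$nucleotides) %/% 3L,
              nrow(x$genes)))
  invisible(x)
}
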