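#' Read motifs from MEME minimal motif format
#'
#' Parses the MEME Suite "minimal" motif interchange format: a `MEME version`
#' line, optional `ALPHABET=` and `Background letter frequencies` blocks, and
#' one `MOTIF` block per motif with a `letter-probability matrix:` header.
#' Full MEME output files are read for their headers and matrices; any other
#' blocks are ignored. All motifs are returned with frequency semantics.
#'
#' @param file Path to a MEME-format file, or a character vector of lines
#'   (anything containing a newline is treated as literal text).
#' @return A [motif_set()].
#' @export
read_meme <- function(file) {
  lines <- read_text_input(file)
  if (!any(grepl("^\\s*MEME version", lines))) {
    rlang::abort("Not MEME format: missing 'MEME version' line.", class = "ttl_format_error")
  }
  lines <- trimws(lines)

  alphabet <- c("A", "C", "G", "T")
  ai <- grep("^ALPHABET=", lines)
  if (length(ai) > 0) {
    alphabet <- strsplit(sub("^ALPHABET=\\s*", "", lines[ai[1]]), "")[[1]]
  }
  A <- length(alphabet)

  background <- rep(1 / A, A)
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi) > 0) {
    # background may wrap over several "letter freq letter freq" lines
    toks <- character(0)
    j <- bi[1] + 1
    while (j <= length(lines) && !grepl("^(MOTIF|ALPHABET|URL|\\s*$)", lines[j])) {
      toks <- c(toks, strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1
    }
    if (length(toks) >= 2 * A) {
      bg <- as.numeric(toks[seq(2, 2 * A, by = 2)])
      names(bg) <- toks[seq(1, 2 * A - 1, by = 2)]
      background <- as.double(bg[alphabet])
      background <- background / sum(background)
    }
  }

  starts <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    if (is.na(name)) {
      rlang::abort("MOTIF line without an identifier.", class = "ttl_format_error")
    }
    end <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    block <- lines[i:end]
    hi <- grep("^letter-probability matrix:", block)
    if (length(hi) == 0) {
      rlang::abort(
        sprintf("Motif '%s': missing 'letter-probability matrix:' header.", name),
        class = "ttl_format_error"
      )
    }
    header <- block[hi[1]]
    decl_alen <- meme_header_field(header, "alength")
    decl_w <- meme_header_field(header, "w")

    rows <- list()
    j <- hi[1] + 1
    while (j <= length(block)) {
      ln <- block[j]
      if (!nzchar(ln)) {
        if (length(rows) > 0) break
        j <- j + 1
        next
      }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(vals)) break
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    if (length(rows) == 0) {
      rlang::abort(sprintf("Motif '%s': empty matrix.", name), class = "ttl_shape_error")
    }
    nvals <- lengths(rows)
    if (length(unique(nvals)) != 1 || (!is.na(decl_alen) && nvals[1] != decl_alen)) {
      rlang::abort(
        sprintf("Motif '%s': matrix row length does not match alength.", name),
        class = "ttl_shape_error"
      )
    }
    if (!is.na(decl_w) && length(rows) != decl_w) {
      rlang::abort(
        sprintf(
          "Motif '%s': header declares w= %d but %d matrix rows found.",
          name, decl_w, length(rows)
        ),
        class = "ttl_shape_error"
      )
    }
    mat <- t(do.call(rbind, rows)) # file rows are positions; store A x W
    if (nrow(mat) != A) {
      rlang::abort(
        sprintf("Motif '%s': %d columns per row but alphabet has %d symbols.", name, nrow(mat), A),
        class = "ttl_shape_error"
      )
    }
    motifs[[k]] <- motif(name, mat,
      alphabet = alphabet, semantics = "frequency",
      background = background
    )
  }
  motif_set(motifs, source = if (length(file) == 1 && !grepl("\n", file)) file else "text")
}

meme_header_field <- function(header, field) {
  m <- regmatches(header, regexec(paste0("\\b", field, "=\\s*(\\d+)"), header))[[1]]
  if (length(m) == 2) as.integer(m[2]) else NA_integer_
}

#' Write a motif set in MEME minimal motif format
#'
#' Entries are written with six decimal places, so a write/read round trip
#' reproduces each value within `1e-6`. A background line is always emitted.
#' Attribution motifs cannot be represented as letter probabilities; use
#' [write_cwm_tsv()] for those.
#'
#' @param s A [motif_set()] of frequency motifs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(s, path) {
  stopifnot(inherits(s, "ttl_motif_set"))
  sem <- vapply(s$motifs, function(m) m$semantics, "")
  if (any(sem != "frequency")) {
    rlang::abort(
      "MEME format stores letter probabilities; write attribution motifs with write_cwm_tsv().",
      class = "ttl_semantics_error"
    )
  }
  alphabet <- set_alphabet(s)
  bg <- if (length(s$motifs) > 0) s$motifs[[1]]$background else rep(1 / length(alphabet), length(alphabet))
  out <- c(
    "MEME version 4", "",
    paste0("ALPHABET= ", paste(alphabet, collapse = "")), "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", alphabet, bg), collapse = " "), ""
  )
  for (m in s$motifs) {
    w <- motif_width(m)
    out <- c(
      out,
      paste("MOTIF", m$name),
      sprintf("letter-probability matrix: alength= %d w= %d", nrow(m$matrix), w),
      vapply(
        seq_len(w),
        function(j) paste(sprintf("%.6f", m$matrix[, j]), collapse = " "),
        ""
      ),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Read motifs from JASPAR-style PFM text
#'
#' Accepts records of a `>name` header followed by one count row per alphabet
#' letter, in either the bracketed dialect (`A [ 4 19 0 ... ]`) or plain
#' whitespace-separated rows. Counts are normalised per column into
#' frequencies; an all-zero column is mapped to the uniform column with a
#' warning (keeps real databases loadable).
#'
#' @param file Path or character vector of lines (text if it contains `\n`).
#' @param alphabet Row order of the counts; default `A,C,G,T`.
#' @return A [motif_set()] with frequency semantics.
#' @export
read_jaspar_pfm <- function(file, alphabet = c("A", "C", "G", "T")) {
  lines <- trimws(read_text_input(file))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) {
    rlang::abort("No '>' record headers found.", class = "ttl_format_error")
  }
  A <- length(alphabet)
  motifs <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    i <- heads[k]
    end <- if (k < length(heads)) heads[k + 1] - 1 else length(lines)
    name <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    body <- lines[(i + 1):end]
    if (length(body) != A) {
      rlang::abort(
        sprintf("Record '%s': expected %d count rows, found %d.", name, A, length(body)),
        class = "ttl_format_error"
      )
    }
    counts <- lapply(body, function(ln) {
      ln <- gsub("^[A-Za-z]\\s*\\[|\\]\\s*$", "", ln) # strip "A [ ... ]"
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(v)) {
        rlang::abort(
          sprintf("Record '%s': non-numeric counts.", name),
          class = "ttl_format_error"
        )
      }
      v
    })
    if (length(unique(lengths(counts))) != 1) {
      rlang::abort(
        sprintf("Record '%s': ragged count rows.", name),
        class = "ttl_format_error"
      )
    }
    mat <- do.call(rbind, counts)
    if (any(mat < 0)) {
      rlang::abort(
        sprintf("Record '%s': negative counts.", name),
        class = "ttl_value_error"
      )
    }
    csum <- colSums(mat)
    if (any(csum == 0)) {
      rlang::warn(sprintf(
        "Record '%s': %d all-zero column(s) set to uniform.",
        name, sum(csum == 0)
      ))
      mat[, csum == 0] <- 1 / A
      csum[csum == 0] <- 1
    }
    mat <- sweep(mat, 2, csum, "/")
    motifs[[k]] <- motif(name, mat, alphabet = alphabet, semantics = "frequency")
  }
  motif_set(motifs, source = if (length(file) == 1 && !grepl("\n", file)) file else "text")
}

#' Write attribution (CWM) motifs as a long TSV sidecar
#'
#' MEME format presumes letter probabilities, so attribution matrices are
#' serialised in a simple long TSV with columns `motif`, `letter`,
#' `position`, `value`, plus a `semantics` column so frequency sets round
#' trip through the same format.
#'
#' @param s A [motif_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cwm_tsv <- function(s, path) {
  stopifnot(inherits(s, "ttl_motif_set"))
  tb <- purrr::map_dfr(s$motifs, function(m) {
    tibble::tibble(
      motif = m$name,
      semantics = m$semantics,
      letter = rep(m$alphabet, times = motif_width(m)),
      position = rep(seq_len(motif_width(m)), each = nrow(m$matrix)),
      value = as.vector(m$matrix)
    )
  })
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a CWM sidecar TSV written by [write_cwm_tsv()]
#' @param file Path to the TSV.
#' @return A [motif_set()].
#' @export
read_cwm_tsv <- function(file) {
  tb <- readr::read_tsv(file, show_col_types = FALSE)
  motifs <- lapply(split(tb, factor(tb$motif, levels = unique(tb$motif))), function(d) {
    alphabet <- unique(d$letter[d$position == 1])
    mat <- matrix(d$value, nrow = length(alphabet))
    motif(d$motif[1], mat, alphabet = alphabet, semantics = d$semantics[1])
  })
  motif_set(unname(motifs), source = if (is.character(file)) file else "tsv")
}

#' Write a hit table as TSV
#'
#' Columns follow the reference vocabulary: `Query_ID`, `Target_ID`,
#' `Optimal_offset`, `p-value`, `E-value`, `q-value`, `Overlap`,
#' `Orientation`.
#'
#' @param hits A hit table from [tomtom()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    Query_ID = hits$query,
    Target_ID = hits$target,
    Optimal_offset = hits$offset,
    `p-value` = hits$p_value,
    `E-value` = hits$e_value,
    `q-value` = hits$q_value,
    Overlap = hits$overlap,
    Orientation = hits$orientation
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# Accept a path or literal text (anything containing a newline, or a
# multi-element character vector, is treated as lines of text).
read_text_input <- function(file) {
  if (length(file) > 1) {
    return(as.character(file))
  }
  if (grepl("\n", file)) {
    return(strsplit(file, "\n", fixed = TRUE)[[1]])
  }
  readLines(file, warn = FALSE)
}
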