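#' @title The GSuite track-collection format
#' @description
#' A GSuite file is a plain-text tabular representation of a suite of
#' tracks. The dialect implemented here is:
#' * header lines `##key: value` (keys case-insensitive, unique; recognized
#'   keys: `location` (local|remote|multiple), `file-format`, `track-type`,
#'   `genome`; unknown keys are preserved verbatim);
#' * an optional single column-declaration line `#uri<TAB>title<TAB>...`
#'   whose first two columns must be `uri` and `title`;
#' * tab-separated data rows, one per track, with `.` for a missing
#'   metadata value;
#' * with no `#` lines at all, a plain text file of one URL per line is a
#'   valid GSuite (the degenerate bare-URL form; titles default to the
#'   basename of the URI).
#' @name gsuite-format
NULL

.gsuite_known_headers <- c("location", "file-format", "track-type", "genome")

#' Construct a GSuite in memory
#'
#' @param uris character vector of track URIs (file paths or URLs).
#' @param titles track titles; default basenames of the URIs.
#' @param metadata data.frame of per-track metadata columns (may have zero
#'   columns); `NA` represents a missing value.
#' @param headers named character vector of header key-value pairs
#'   (keys lower-cased).
#' @return object of class `gsuite` with fields `headers`, `tracks`
#'   (data.frame `uri`, `title`, plus metadata columns) and `n`.
#' @export
gsuite <- function(uris, titles = NULL, metadata = NULL, headers = character()) {
  uris <- as.character(uris)
  if (any(!nzchar(uris))) stop("empty uri")
  if (is.null(titles))
    titles <- tools::file_path_sans_ext(basename(uris))
  titles <- as.character(titles)
  stopifnot(length(titles) == length(uris))
  if (is.null(metadata))
    metadata <- as.data.frame(matrix(nrow = length(uris), ncol = 0))
  stopifnot(is.data.frame(metadata), nrow(metadata) == length(uris))
  if (any(c("uri", "title") %in% names(metadata)))
    stop("metadata columns may not be named 'uri' or 'title'")
  if (length(headers) > 0) {
    if (is.null(names(headers)) || any(!nzchar(names(headers))))
      stop("headers must be a named character vector")
    names(headers) <- tolower(names(headers))
    if (anyDuplicated(names(headers))) stop("duplicate header keys")
  }
  tracks <- cbind(data.frame(uri = uris, title = titles,
                             stringsAsFactors = FALSE), metadata)
  rownames(tracks) <- NULL
  structure(list(headers = headers, tracks = tracks, n = length(uris)),
            class = "gsuite")
}

#' @export
print.gsuite <- function(x, ...) {
  meta <- setdiff(names(x$tracks), c("uri", "title"))
  cat(sprintf("<gsuite: %d tracks, %d header(s), metadata columns: %s>\n",
              x$n, length(x$headers),
              if (length(meta)) paste(meta, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Parse a GSuite file
#'
#' @param path path to a GSuite file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text interpret `path` as the file content itself.
#' @return a [gsuite()] object.
#' @export
parse_gsuite <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(path, "\n", fixed = TRUE))
           else readLines(path, warn = FALSE)
  headers <- character()
  columns <- NULL
  rows <- list(); row_lines <- integer()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "##")) {
      if (!is.null(columns) || length(rows) > 0)
        stop(sprintf("line %d: header after column declaration or data", i))
      kv <- sub("^##", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
      if (length(m) != 3)
        stop(sprintf("line %d: malformed header line '%s'", i, ln))
      key <- tolower(trimws(m[2]))
      if (key %in% names(headers))
        stop(sprintf("line %d: duplicate header key '%s'", i, key))
      headers[key] <- trimws(m[3])
    } else if (startsWith(ln, "#")) {
      if (!is.null(columns))
        stop(sprintf("line %d: multiple column declaration lines", i))
      if (length(rows) > 0)
        stop(sprintf("line %d: column declaration after data rows", i))
      columns <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      if (length(columns) < 1 || columns[1] != "uri")
        stop(sprintf("line %d: first declared column must be 'uri'", i))
      if (length(columns) >= 2 && columns[2] != "title")
        stop(sprintf("line %d: second declared column must be 'title'", i))
      if (anyDuplicated(columns))
        stop(sprintf("line %d: duplicate column names", i))
    } else {
      rows[[length(rows) + 1]] <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      row_lines[length(rows)] <- i
    }
  }
  if (is.null(columns)) {
    # bare-URL form: each data line is a single uri
    bad <- which(lengths(rows) != 1)
    if (length(bad) > 0)
      stop(sprintf("line %d: tab-separated row without a column declaration",
                   row_lines[bad[1]]))
    uris <- vapply(rows, `[[`, character(1), 1)
    return(gsuite(uris, headers = headers))
  }
  nc <- length(columns)
  bad <- which(lengths(rows) != nc)
  if (length(bad) > 0)
    stop(sprintf("line %d: expected %d fields, found %d",
                 row_lines[bad[1]], nc, length(rows[[bad[1]]])))
  mat <- do.call(rbind, rows)
  uris <- mat[, 1]
  titles <- if (nc >= 2) mat[, 2] else NULL
  meta <- if (nc >= 3) {
    md <- as.data.frame(mat[, 3:nc, drop = FALSE], stringsAsFactors = FALSE)
    names(md) <- columns[3:nc]
    md[md == "."] <- NA
    md
  } else NULL
  gsuite(uris, titles = titles, metadata = meta, headers = headers)
}

#' Write a GSuite file
#'
#' `parse_gsuite(write_gsuite(s))` reproduces `s` exactly, including header
#' order. Missing metadata values are written as `.`. A literal tab inside
#' a value cannot be represented and is an error.
#'
#' @param x a `gsuite`.
#' @param path output path.
#' @export
write_gsuite <- function(x, path) {
  stopifnot(inherits(x, "gsuite"))
  vals <- unlist(lapply(x$tracks, as.character))
  if (any(grepl("\t", vals[!is.na(vals)], fixed = TRUE)))
    stop("tab character inside a GSuite field cannot be escaped")
  out <- character(0)
  if (length(x$headers) > 0)
    out <- c(out, sprintf("##%s: %s", names(x$headers), unname(x$headers)))
  cols <- names(x$tracks)
  out <- c(out, paste0("#", paste(cols, collapse = "\t")))
  body <- x$tracks
  for (j in seq_along(body)) {
    v <- as.character(body[[j]])
    v[is.na(v)] <- "."
    body[[j]] <- v
  }
  out <- c(out, do.call(paste, c(unname(as.list(body)), sep = "\t")))
  writeLines(out, path)
  invisible(NULL)
}

#' Validate a GSuite against a genome
#'
#' Collects per-track problems without aborting on the first: remote URIs
#' (retrieval is unsupported here), missing local files, unparseable BED
#' content, and intervals not resolving against the genome.
#'
#' @param x a `gsuite`.
#' @param genome optional `genome_def` to validate track content against.
#' @param check_files check that local files exist and parse (default TRUE).
#' @return data.frame with columns `uri`, `title`, `problem`
#'   (zero rows when the suite is clean).
#' @export
validate_gsuite <- function(x, genome = NULL, check_files = TRUE) {
  stopifnot(inherits(x, "gsuite"))
  probs <- list()
  add <- function(uri, title, problem)
    probs[[length(probs) + 1]] <<- data.frame(uri = uri, title = title,
                                              problem = problem,
                                              stringsAsFactors = FALSE)
  for (i in seq_len(x$n)) {
    uri <- x$tracks$uri[i]; title <- x$tracks$title[i]
    if (grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", uri) &&
        !startsWith(uri, "file://")) {
      if (check_files)
        add(uri, title, "remote retrieval unsupported; fetch the file first")
      next
    }
    if (!check_files) next
    p <- sub("^file://", "", uri)
    if (!file.exists(p)) {
      add(uri, title, "local file not found")
      next
    }
    res <- tryCatch({
      if (is.null(genome)) .read_bed_df(p) else read_bed(p, genome)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(uri, title, res)
  }
  if (length(probs) == 0)
    data.frame(uri = character(), title = character(), problem = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, probs)
}

#' Filter a GSuite on metadata
#'
#' Evaluates an expression in the context of the track table (columns
#' `uri`, `title` and all metadata columns) and keeps the matching tracks in
#' order; `complement = TRUE` keeps the non-matching ones instead, so filter
#' plus complement partition the suite.
#'
#' @param x a `gsuite`.
#' @param expr a filtering expression, e.g. `antibody == "GATA1"`.
#' @param complement return the non-matching tracks instead.
#' @return a `gsuite` (possibly with `n = 0`, in which case a warning is
#'   emitted and the attribute `empty_selection` is set).
#' @examples
#' s <- gsuite(c("a.bed", "b.bed"),
#'             metadata = data.frame(antibody = c("GATA1", "TAL1")))
#' filter_gsuite(s, antibody == "GATA1")$n
#' @export
filter_gsuite <- function(x, expr, complement = FALSE) {
  stopifnot(inherits(x, "gsuite"))
  e <- substitute(expr)
  used <- all.vars(e)
  unknown <- setdiff(used, names(x$tracks))
  if (length(unknown) > 0)
    stop("unknown metadata column: ", paste(unknown, collapse = ", "))
  keep <- eval(e, envir = x$tracks, enclos = parent.frame())
  if (!is.logical(keep) || length(keep) != x$n)
    stop("filter expression must yield one logical per track")
  keep[is.na(keep)] <- FALSE
  if (complement) keep <- !keep
  sel <- x$tracks[keep, , drop = FALSE]
  meta <- sel[, setdiff(names(sel), c("uri", "title")), drop = FALSE]
  rownames(meta) <- NULL
  out <- structure(list(headers = x$headers,
                        tracks = { rownames(sel) <- NULL; sel },
                        n = nrow(sel)),
                   class = "gsuite")
  if (out$n == 0) {
    warning("filter matched no tracks")
    attr(out, "empty_selection") <- TRUE
  }
  out
}

#' Load all tracks of a local GSuite
#'
#' @param x a `gsuite` whose URIs are local, readable BED files.
#' @param genome a `genome_def`.
#' @return list of [track()] objects in suite order, labelled by title
#'   (duplicate titles are disambiguated with an index suffix, with a
#'   warning).
#' @export
load_suite_tracks <- function(x, genome) {
  stopifnot(inherits(x, "gsuite"), inherits(genome, "genome_def"))
  remote <- grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", x$tracks$uri) &
    !startsWith(x$tracks$uri, "file://")
  if (any(remote))
    stop("remote uri in suite ('", x$tracks$uri[which(remote)[1]],
         "'): fetch the file first")
  labels <- x$tracks$title
  dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate track titles disambiguated with an index suffix")
    labels[dup] <- sprintf("%s.%d", labels[dup], seq_len(x$n)[dup])
  }
  lapply(seq_len(x$n), function(i) {
    p <- sub("^file://", "", x$tracks$uri[i])
    tryCatch(read_bed(p, genome, label = labels[i]),
             error = function(e)
               stop("track '", x$tracks$title[i], "': ",
                    conditionMessage(e), call. = FALSE))
  })
}
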