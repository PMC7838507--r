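# Minimal static HTTP server over base-R server sockets, run as a background
# Rscript worker, plus a curl-based fetcher. The transport contract is plain
# HTTP/1.1 GET of exact file bytes: GET /metadata.json and GET of any
# bitblock_relpath() return 200 with the on-disk bytes; anything else is 404.
# One control endpoint, GET /__stop__, shuts the worker down; the worker also
# exits on its own after `idle_timeout` seconds without a request so stray
# processes never outlive a session.

#' Serve a dataset tree over HTTP
#'
#' `serve()` starts a background worker process serving static GETs from
#' `root` on the loopback interface and blocks until the server answers
#' `/metadata.json`. `stop_server()` shuts it down. `serve_blocking()` is the
#' worker loop itself (exported so the worker process can call it; it does
#' not return until stopped).
#'
#' @param root Directory containing `metadata.json` and the bitBlock tree.
#' @param port TCP port; 0 picks a random free port.
#' @param idle_timeout Seconds without a request after which the worker
#'   exits on its own.
#' @return `serve()` returns a handle of class `bitvox_server` with fields
#'   `url`, `port`, `root` and `pid`.
#' @export
serve <- function(root, port = 0L, idle_timeout = 600) {
  if (!file.exists(file.path(root, "metadata.json"))) {
    stop("`root` does not contain metadata.json", call. = FALSE)
  }
  rscript <- file.path(R.home("bin"), "Rscript")
  for (attempt in 1:5) {
    p <- if (port > 0) as.integer(port) else sample(20000:60000, 1)
    pidfile <- tempfile(fileext = ".pid")
    expr <- sprintf(
      "bitvox::serve_blocking(%s, %dL, pidfile = %s, idle_timeout = %d)",
      deparse(normalizePath(root)), p, deparse(pidfile),
      as.integer(idle_timeout))
    system2(rscript, c("--vanilla", "-e", shQuote(expr)),
            stdout = FALSE, stderr = FALSE, wait = FALSE)
    url <- sprintf("http://127.0.0.1:%d", p)
    deadline <- Sys.time() + 15
    while (Sys.time() < deadline) {
      ok <- tryCatch({
        h <- curl::new_handle(timeout = 2)
        res <- curl::curl_fetch_memory(paste0(url, "/metadata.json"), h)
        res$status_code == 200
      }, error = function(e) FALSE)
      if (isTRUE(ok)) {
        pid <- if (file.exists(pidfile)) {
          suppressWarnings(as.integer(readLines(pidfile, warn = FALSE)[1]))
        } else NA_integer_
        return(structure(list(url = url, port = p, root = root, pid = pid),
                         class = "bitvox_server"))
      }
      Sys.sleep(0.1)
    }
    if (port > 0) stop("server failed to start on port ", port, call. = FALSE)
  }
  stop("server failed to start after 5 port attempts", call. = FALSE)
}

#' @rdname serve
#' @param handle A `bitvox_server` handle from `serve()`.
#' @export
stop_server <- function(handle) {
  stopifnot(inherits(handle, "bitvox_server"))
  tryCatch({
    h <- curl::new_handle(timeout = 2)
    curl::curl_fetch_memory(paste0(handle$url, "/__stop__"), h)
  }, error = function(e) NULL)
  # belt and braces: if the polite shutdown raced, kill the worker
  if (!is.na(handle$pid)) {
    Sys.sleep(0.05)
    suppressWarnings(tools::pskill(handle$pid))
  }
  invisible(TRUE)
}

#' @rdname serve
#' @param pidfile Optional path where the worker writes its process id.
#' @export
serve_blocking <- function(root, port, pidfile = NULL, idle_timeout = 600) {
  root <- normalizePath(root, mustWork = TRUE)
  sv <- serverSocket(as.integer(port))
  on.exit(close(sv), add = TRUE)
  if (!is.null(pidfile)) writeLines(as.character(Sys.getpid()), pidfile)
  repeat {
    ready <- socketSelect(list(sv), timeout = idle_timeout)
    if (!any(ready)) return(invisible(FALSE))        # idle: give up the port
    con <- tryCatch(socketAccept(sv, blocking = TRUE, open = "a+b",
                                 timeout = 10),
                    error = function(e) NULL)
    if (is.null(con)) next
    stop_requested <- tryCatch(handle_request(con, root),
                               error = function(e) FALSE)
    tryCatch(close(con), error = function(e) NULL)
    if (isTRUE(stop_requested)) return(invisible(TRUE))
  }
}

# Read one request from `con`, write the response. Returns TRUE if the
# request was the stop control endpoint.
handle_request <- function(con, root) {
  req <- readLines(con, n = 1)
  if (!length(req)) return(FALSE)
  # drain headers
  while (length(l <- readLines(con, n = 1)) && nzchar(l)) {}
  parts <- strsplit(req, " ", fixed = TRUE)[[1]]
  if (length(parts) < 2L || parts[1] != "GET") {
    respond(con, 405L, charToRaw("method not allowed\n"))
    return(FALSE)
  }
  path <- utils::URLdecode(sub("\\?.*$", "", parts[2]))
  if (path == "/__stop__") {
    respond(con, 200L, charToRaw("bye\n"))
    return(TRUE)
  }
  rel <- sub("^/+", "", path)
  fp <- file.path(root, rel)
  ok <- nzchar(rel) && !grepl("\\.\\.", rel, fixed = FALSE) &&
    file.exists(fp) && !dir.exists(fp) &&
    startsWith(normalizePath(fp, mustWork = FALSE), root)
  if (!ok) {
    respond(con, 404L, charToRaw("not found\n"))
    return(FALSE)
  }
  respond(con, 200L, readBin(fp, "raw", n = file.size(fp)))
  FALSE
}

respond <- function(con, status, body) {
  msg <- c(`200` = "OK", `404` = "Not Found", `405` = "Method Not Allowed")
  writeLines(c(sprintf("HTTP/1.1 %d %s", status,
                       msg[[as.character(status)]]),
               "Content-Type: application/octet-stream",
               sprintf("Content-Length: %d", length(body)),
               "Connection: close", ""),
             con, sep = "\r\n")
  writeBin(body, con)
  flush(con)
}

#' @export
print.bitvox_server <- function(x, ...) {
  cat(sprintf("bitvox server at %s (root %s, pid %s)\n", x$url, x$root,
              x$pid))
  invisible(x)
}

# GET a URL; 404 -> bitvox_not_found, other failures retried.
fetch_url <- function(url, retries = 3L) {
  last <- NULL
  for (attempt in seq_len(retries)) {
    res <- tryCatch({
      h <- curl::new_handle(timeout = 10)
      curl::curl_fetch_memory(url, h)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      if (res$status_code == 200) return(res$content)
      if (res$status_code == 404) {
        stop(errorCondition(paste0("not found: ", url),
                            class = c("bitvox_not_found", "error")))
      }
      last <- simpleError(paste0("HTTP ", res$status_code, " for ", url))
    } else {
      last <- res
    }
    Sys.sleep(0.2 * attempt)
  }
  stop(errorCondition(
    paste0("transport error fetching ", url, ": ", conditionMessage(last)),
    class = c("bitvox_transport_error", "error")))
}

#' Fetch one bitBlock over HTTP
#'
#' Downloads and decodes the bitBlock at `ref` from a served dataset;
#' observationally equivalent to [read_bitblock()] on the server's local
#' store. Transient transport failures are retried (default 3 attempts);
#' a 404 raises a `bitvox_not_found` condition.
#'
#' @param base_url Server base URL, e.g. `"http://127.0.0.1:8080"`.
#' @param ref A [bitplane_ref()].
#' @param retries Attempts before giving up with `bitvox_transport_error`.
#' @return A `bitvox_bitplane`.
#' @export
fetch_bitblock <- function(base_url, ref, retries = 3L) {
  relpath <- bitblock_relpath(ref)
  bytes <- fetch_url(paste0(sub("/+$", "", base_url), "/", relpath),
                     retries = retries)
  decode_bitblock_tiff(tiff::readTIFF(bytes, as.is = TRUE), ref, relpath)
}
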