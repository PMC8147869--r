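# Thin bridge to the bundled python helper scripts. All traffic is batched
# JSON through temp files; one python process per batch keeps the startup
# cost (rdkit / sklearn import) amortized over whole vectors of molecules.

promsets_python <- function() {
  py <- getOption("promsets.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("no python interpreter found; set options(promsets.python=...)",
         call. = FALSE)
  }
  py
}

py_script <- function(name) {
  path <- system.file("python", name, package = "promsets")
  if (!nzchar(path)) {
    # during devtools::load_all() the package root is inst/
    path <- file.path("inst", "python", name)
  }
  if (!file.exists(path)) stop("helper script not found: ", name, call. = FALSE)
  path
}

run_py <- function(script, args, payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA, null = "null")
  res <- suppressWarnings(system2(
    promsets_python(), c(shQuote(py_script(script)), args, shQuote(fin), shQuote(fout)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("python helper '", script, "' failed:\n", paste(res, collapse = "\n"),
         call. = FALSE)
  }
  jsonlite::read_json(fout)
}

chemtools <- function(command, payload) run_py("chemtools.py", command, payload)
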