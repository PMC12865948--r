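# Shared internal helpers: condition classes, seeded RNG scope, logging.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
.CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "CBM", "AA")
.HYD_GROUPS <- c("[NiFe]", "[FeFe]", "[Fe]")
.HYD_CATEGORIES <- c("fermentative", "electron-bifurcating", "sensory",
                     "methanogenic", "respiratory", "energy-converting")
.UNASSIGNED <- "unassigned"

# All package errors inherit "ftx_error" so the CLI can map them to exit
# code 2 (user/input error) while anything else maps to 1 (internal).
ftx_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ftx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
ftx_usage_error  <- function(msg) ftx_error(msg, "ftx_usage_error")
ftx_format_error <- function(msg) ftx_error(msg, "ftx_format_error")
ftx_design_error <- function(msg) ftx_error(msg, "ftx_design_error")
ftx_spec_error   <- function(msg) ftx_error(msg, "ftx_spec_error")
ftx_io_error     <- function(msg) ftx_error(msg, "ftx_io_error")

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. Every randomized operation in the package funnels through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    ftx_usage_error("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

ftx_log <- function(..., quiet = getOption("funtaxa.quiet", FALSE)) {
  if (!isTRUE(quiet)) message("[funtaxa] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_wholenumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}
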