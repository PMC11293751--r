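# internal helpers

# run code with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# package-level logging: messages to stderr, optionally teed to a file
mriseg_log <- function(fmt, ..., file = getOption("mriseg.log_file", NULL)) {
  line <- sprintf("[mriseg %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
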