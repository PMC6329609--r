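# scenario runs shared across test files (computed once per session)
.runCache <- new.env(parent = emptyenv())

cachedScenario <- function(name, ...) {
  if (!exists(name, envir = .runCache))
    assign(name, runScenario(name, ...), envir = .runCache)
  get(name, envir = .runCache)
}

# small tissue helpers used by several files
zeroMorphogenProgram <- function() morphogenProgram("static", xi = 0.01)

fmtFates <- function(pattern) {
  f <- pattern@fates
  paste(ifelse(is.na(f), ".", ifelse(f == 0, "-", f)), collapse = "")
}

onsetsFromTrajectory <- function(traj, level, dtOut = 0.1) {
  apply(traj, 2, function(x) {
    i <- which(x >= level)[1]
    if (is.na(i)) NA_real_ else (i - 1) * dtOut
  })
}
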