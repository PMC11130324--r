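## Shared fixtures: networks and steady states are expensive enough to
## build once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

skbr3Vitro <- function() cached("vitro", buildNetwork(cellLineConfig("SKBR3")))

skbr3VitroSS <- function() cached("vitroSS", initializeSteadyState(skbr3Vitro()))

skbr3Vivo <- function() cached("vivo", buildNetwork(
  cellLineConfig("SKBR3", growth = growthDeathParams(inVivo = TRUE)),
  inVitro = FALSE))

## last value of a readout after simulating a stimulus from steady state
endReadout <- function(stim, name, duration = 24, network = skbr3Vitro(),
                       ss = skbr3VitroSS()) {
  tr <- simulateTimecourse(network, ss, stim, duration,
                           dt = duration / 24)
  ro <- readout(tr, name)
  unname(ro[length(ro)])
}

## readout at a specific hour
readoutAt <- function(stim, name, hour, duration = max(2, hour),
                      network = skbr3Vitro(), ss = skbr3VitroSS()) {
  tr <- simulateTimecourse(network, ss, stim, duration, dt = 0.25)
  unname(readout(tr, name)[which(trajTimes(tr) >= hour)[1]])
}

tgiAtDay <- function(reg, day = 20, network = skbr3Vivo(),
                     stim = stimulus()) {
  trt <- runXenograft(network, reg, day + 1, stim0 = stim)
  ctl <- runXenograft(network, regimen(), day + 1, stim0 = stim)
  computeTGI(trt, ctl, day)
}
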