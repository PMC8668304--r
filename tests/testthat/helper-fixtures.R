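# Shared small fixtures, generated in code at test time.

quietSpec <- function(hw = 64, radius = 8, sigma = 0.05, seed = 1,
                      tumor = list(), noise = list(), ...) {
  phantomSpec(hw, hw,
              tumor = utils::modifyList(list(radiusPx = radius), tumor),
              noise = utils::modifyList(list(sigma = sigma), noise),
              seed = seed, ...)
}

# a tiny easy dataset for learning-sanity tests (cached per session)
.fixtureEnv <- new.env()

easyDataset <- function(n = 40, hw = 32, seed = 101) {
  key <- paste0("easy", n, "_", hw, "_", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateDataset(
      n, 0.5, nSubjects = max(2, n %/% 5),
      baseSpec = phantomSpec(hw, hw, tumor = list(radiusPx = hw %/% 6),
                             noise = list(sigma = 0.02)),
      seed = seed)
  .fixtureEnv[[key]]
}
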