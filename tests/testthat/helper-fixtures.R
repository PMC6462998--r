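# Shared fixtures. The default network is expensive enough (~2 s) to build
# once per test session.

.fixtures <- new.env(parent = emptyenv())

defaultNetwork <- function() {
  if (is.null(.fixtures$net)) .fixtures$net <- assembleNetwork()
  .fixtures$net
}

# small luminance stack: a bright centered disc over mid-frames, dark after
discFrames <- function(sizePx = 120, nOn = 9, nOff = 9, radius = 12,
                       frameInterval = 100 / 3) {
  nf <- nOn + nOff
  fr <- array(0, dim = c(nf, sizePx, sizePx))
  ctr <- (sizePx + 1) / 2
  d <- sqrt(outer(((1:sizePx) - ctr)^2, ((1:sizePx) - ctr)^2, "+"))
  disc <- ifelse(d <= radius, 1, 0)
  for (f in seq_len(nOn)) fr[f, , ] <- disc
  new("FrameSequence", frames = fr, frameInterval = frameInterval,
      pxPerDegree = defaultPxPerDegree(), metadata = list(kind = "disc"))
}

zeroFrames <- function(sizePx = 120, nf = 6, frameInterval = 100 / 3) {
  new("FrameSequence", frames = array(0, dim = c(nf, sizePx, sizePx)),
      frameInterval = frameInterval, pxPerDegree = defaultPxPerDegree(),
      metadata = list(kind = "blank"))
}

spikeDataOf <- function(neuron, time, n, duration = max(time, 1)) {
  new("SpikeData", layer = "test",
      events = data.frame(neuron = neuron, time = time),
      n = as.integer(n), duration = duration)
}
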