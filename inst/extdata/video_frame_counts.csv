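species,n_videos,n_frames
lotus,15,134865
trifolium,18,154151
persicaria,15,129145
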