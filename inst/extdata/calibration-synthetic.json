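{
  "description": "Calibration of the synthetic generator's effect sizes: single-branch and fused held-out-episode accuracy under the compact study configuration (64 Hz, 8 channels, 3 episodes x 40 s per state, 20 epochs), 3 seeds per cell, episode_shift = 0. Basis for the frozen defaults eeg_effect = 0.8, ecg_effect = 0.8.",
  "conditions": {
    "fs": 64,
    "n_eeg_channels": 8,
    "n_episodes": 3,
    "seg_seconds_per_state": 40,
    "epochs": 20,
    "batch_size": 16,
    "lr": 0.003
  },
  "grid": [
    {
      "eeg_effect": 0,
      "ecg_effect": 0,
      "episode_shift": 0,
      "seeds": 3,
      "mean_eeg_branch_acc": 0.4917,
      "mean_ecg_branch_acc": 0.5139,
      "mean_fused_acc": 0.5042
    },
    {
      "eeg_effect": 0.8,
      "ecg_effect": 0.8,
      "episode_shift": 0,
      "seeds": 3,
      "mean_eeg_branch_acc": 0.8069,
      "mean_ecg_branch_acc": 0.725,
      "mean_fused_acc": 0.9069
    },
    {
      "eeg_effect": 1.6,
      "ecg_effect": 1.6,
      "episode_shift": 0,
      "seeds": 3,
      "mean_eeg_branch_acc": 0.8833,
      "mean_ecg_branch_acc": 0.9153,
      "mean_fused_acc": 0.9861
    },
    {
      "eeg_effect": 2.5,
      "ecg_effect": 2.5,
      "episode_shift": 0,
      "seeds": 3,
      "mean_eeg_branch_acc": 0.8722,
      "mean_ecg_branch_acc": 0.9653,
      "mean_fused_acc": 0.9944
    }
  ]
}
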