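# Registry of supported FMA upper-limb test movements.
#
# Each entry names the movement, its FMA category, the sensors a recording
# must contain, the preprocessing constants, and the feature recipe: an
# ordered list of primitive feature calls whose results are concatenated
# into the classifier input. Frame-based primitives name the skeleton frame
# they are evaluated at (extreme_high / extreme_low = wrist highest/lowest
# after speed normalization; first / last).
version: 1
defaults:
  preprocess:
    target_frames: 30
    movement_threshold: 0.003
    filter_window: 5
    end_quiet_time: 1.0
    gyro_rest_threshold: 5.0
tests:
  - test_id: shoulder_abduction
    label: Shoulder abduction
    category: Shoulder
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: shoulder, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
  - test_id: shoulder_external_rotation
    label: Shoulder external rotation
    category: Shoulder
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: elbow, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
  - test_id: shoulder_abduction_0_90
    label: Shoulder abduction 0-90 deg
    category: Shoulder
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: shoulder, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
  - test_id: shoulder_flexion_0_90
    label: Shoulder flexion 0-90 deg
    category: Shoulder
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: shoulder, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
  - test_id: shoulder_flexion_90_180
    label: Shoulder flexion 90-180 deg
    category: Shoulder
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: shoulder, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
  - test_id: elbow_flexion
    label: Elbow flexion
    category: Elbow
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: elbow, frame: extreme_high}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_high}
      - {feature: limb_orientation, limb: forearm, frame: extreme_high}
  - test_id: elbow_extension
    label: Elbow extension
    category: Elbow
    required_sensors: [skeleton]
    recipe:
      - {feature: joint_angle, vertex: elbow, frame: extreme_low}
      - {feature: limb_orientation, limb: upper_arm, frame: extreme_low}
      - {feature: limb_orientation, limb: forearm, frame: extreme_low}
  - test_id: prosupination_elbow_90
    label: Pronation/supination with elbow at 90 deg
    category: Elbow
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: smoothness}
      - {feature: movement_amount}
  - test_id: prosupination_elbow_0
    label: Pronation/supination with elbow at 0 deg
    category: Elbow
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: smoothness}
      - {feature: movement_amount}
  - test_id: forearm_supination
    label: Forearm supination
    category: Forearm
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: movement_amount}
      - {feature: smoothness}
  - test_id: forearm_pronation
    label: Forearm pronation
    category: Forearm
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: movement_amount}
      - {feature: smoothness}
  - test_id: finger_mass_flexion
    label: Finger mass flexion
    category: Hand
    required_sensors: [glove]
    recipe:
      - {feature: finger_state, mode: flexion}
  - test_id: finger_mass_extension
    label: Finger mass extension
    category: Hand
    required_sensors: [glove]
    recipe:
      - {feature: finger_state, mode: extension}
  - test_id: grasp_a
    label: Grasp a (hook grasp)
    category: Hand
    required_sensors: [glove, pressure]
    recipe:
      - {feature: finger_state, mode: flexion}
      - {feature: grip_strength}
  - test_id: grasp_b
    label: Grasp b (thumb adduction)
    category: Hand
    required_sensors: [glove, pressure]
    recipe:
      - {feature: finger_state, mode: flexion}
      - {feature: grip_strength}
  - test_id: grasp_c
    label: Grasp c (pincer grasp)
    category: Hand
    required_sensors: [glove, pressure]
    recipe:
      - {feature: finger_state, mode: flexion}
      - {feature: grip_strength}
  - test_id: grasp_d
    label: Grasp d (cylinder grasp)
    category: Hand
    required_sensors: [glove, pressure]
    recipe:
      - {feature: finger_state, mode: flexion}
      - {feature: grip_strength}
  - test_id: grasp_e
    label: Grasp e (spherical grasp)
    category: Hand
    required_sensors: [glove, pressure]
    recipe:
      - {feature: finger_state, mode: flexion}
      - {feature: grip_strength}
  - test_id: wrist_flexext_elbow_90
    label: Wrist flexion/extension with elbow at 90 deg
    category: Wrist
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: movement_amount}
  - test_id: wrist_flexext_elbow_0
    label: Wrist flexion/extension with elbow at 0 deg
    category: Wrist
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: movement_amount}
  - test_id: wrist_circumduction
    label: Wrist circumduction
    category: Wrist
    required_sensors: [imu]
    recipe:
      - {feature: rotation_range}
      - {feature: smoothness}
      - {feature: movement_amount}
  - test_id: coordination_tremor
    label: Coordination/speed - tremor
    category: Coordination/Speed
    required_sensors: [imu]
    recipe:
      - {feature: smoothness}
      - {feature: movement_amount}
  - test_id: coordination_speed
    label: Coordination/speed - speed
    category: Coordination/Speed
    required_sensors: [imu]
    recipe:
      - {feature: movement_amount}
      - {feature: smoothness}
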