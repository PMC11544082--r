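<?xml version="1.0" encoding="UTF-8"?>
<TrackMate version="7.0.0">
 <Model spatialunits="micron" timeunits="sec">
 <AllSpots nspots="3">
  <SpotsInFrame frame="0">
   <Spot ID="1000" FRAME="0" POSITION_T="0.0" POSITION_X="12.0" POSITION_Y="3.0" QUALITY="1"/>
  </SpotsInFrame>
  <SpotsInFrame frame="1">
   <Spot ID="1001" FRAME="1" POSITION_T="0.5" POSITION_X="11.2" POSITION_Y="3.1" QUALITY="1"/>
  </SpotsInFrame>
  <SpotsInFrame frame="2">
   <Spot ID="1002" FRAME="2" POSITION_T="1.0" POSITION_X="10.1" POSITION_Y="3.0" QUALITY="1"/>
  </SpotsInFrame>
 </AllSpots>
 <AllTracks>
  <Track TRACK_ID="0" name="Track_0">
   <Edge SPOT_SOURCE_ID="1000" SPOT_TARGET_ID="1001"/>
   <Edge SPOT_SOURCE_ID="1001" SPOT_TARGET_ID="1002"/>
  </Track>
 </AllTracks>
 </Model>
</TrackMate>
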